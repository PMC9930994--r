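# build a small minority cohort with hand-set coherent frequencies so the
# extraction rules can be checked against counting oracles
makeMinority <- function(nPatients, freqsPerPatient) {
  cohort <- list(); analyses <- list()
  for (i in seq_len(nPatients)) {
    id <- sprintf("M%02d", i)
    freqs <- freqsPerPatient[[(i - 1) %% length(freqsPerPatient) + 1]]
    exams <- lapply(setNames(c("horizontal", "anterior", "posterior"),
                             c("horizontal", "anterior", "posterior")),
                    function(scc) lapply(seq_along(freqs), function(j)
                      pureGainTrace(0.5 + 0.1 * j, scc = scc)))
    ri <- vhitwca:::lowerMedianIndex(freqs)
    cohort[[i]] <- new("PatientRecord", patientId = id, outcome = "CR",
                       exams = exams, derived = list())
    analyses[[id]] <- list(outcome = "CR", scc = lapply(exams, function(e)
      list(frequencies = freqs, repIndex = ri, repFrequency = freqs[ri],
           repMap = NULL)))
  }
  list(cohort = cohort, analyses = analyses)
}

test_that("over-sampling copies to the target size deterministically", {
  m <- makeMinority(20, list(c(5, 6, 7)))
  samples <- representativeSamples(m$cohort, m$analyses)
  aug <- augmentOS(samples, 44, seed = 3)
  expect_length(augmentedSamples(aug), 44)
  prov <- provenance(aug)
  expect_equal(sum(prov$type == "OS-copy"), 24)
  expect_equal(sum(prov$type == "original"), 20)
  # copies resolve to existing originals
  expect_true(all(prov$parents[prov$type == "OS-copy"] %in%
                  prov$sample_id[prov$type == "original"]))
  aug2 <- augmentOS(samples, 44, seed = 3)
  expect_identical(provenance(aug2), prov)
  expect_identical(augmentOS(samples, 20)@provenance$type,
                   rep("original", 20))
  expect_error(augmentOS(samples, 10), "below")
})

test_that("EDE extracts the nearest real repeat, ties to the earliest", {
  m <- makeMinority(1, list(c(5.0, 5.9, 6.2)))
  # representative is the (lower) median 5.9; nearest other is 6.2
  aug <- augmentEDE(m$cohort, m$analyses, 2)
  extra <- augmentedSamples(aug)[[2]]
  expect_equal(vorGain(extra$traces$posterior), 0.8, tolerance = 1e-6)
  # tie: representative 6.0 between 5.8 and 6.2 -> earliest repeat wins
  mt <- makeMinority(1, list(c(5.8, 6.0, 6.2)))
  augT <- augmentEDE(mt$cohort, mt$analyses, 2)
  expect_equal(vorGain(augmentedSamples(augT)[[2]]$traces$posterior), 0.6,
               tolerance = 1e-6)
})

test_that("EDE cycles patients round-robin and never fabricates data", {
  m <- makeMinority(20, list(c(5, 6, 7, 8)))
  aug <- augmentEDE(m$cohort, m$analyses, 44)
  prov <- provenance(aug)
  expect_length(augmentedSamples(aug), 44)
  counts <- table(prov$parents[prov$type == "EDE-extract"])
  expect_equal(sum(counts), 24)
  expect_true(all(counts <= 2))           # nobody contributes a 3rd before
  expect_equal(sum(counts == 2), 4)       # exactly four second extractions
  # every extracted trace equals a recorded repeat bit for bit
  for (k in which(prov$type == "EDE-extract")) {
    s <- augmentedSamples(aug)[[k]]
    pat <- m$cohort[[match(prov$parents[k],
                           vapply(m$cohort, patientId, character(1)))]]
    hit <- any(vapply(patientExams(pat)$posterior, function(tr)
      identical(eyeVelocity(tr), eyeVelocity(s$traces$posterior)),
      logical(1)))
    expect_true(hit)
  }
  # exhaustion: 1 spare repeat per patient cannot fill a large target
  m2 <- makeMinority(2, list(c(5, 6)))
  expect_error(augmentEDE(m2$cohort, m2$analyses, 8), "spare")
})

test_that("ITS blends are convex, endpoint-exact and gain-linear", {
  m <- makeMinority(2, list(c(5, 6, 7)))
  samples <- representativeSamples(m$cohort, m$analyses)
  # fixed lambda = 0 -> exact copy of the second parent
  aug0 <- augmentITS(samples, 3, seed = 1, lambda = 0)
  b <- augmentedSamples(aug0)[[3]]
  expect_identical(eyeVelocity(b$traces$horizontal),
                   eyeVelocity(samples[[2]]$traces$horizontal))
  # lambda = 0.5 -> pointwise midpoint
  augH <- augmentITS(samples, 3, seed = 1, lambda = 0.5)
  mid <- augmentedSamples(augH)[[3]]
  expect_equal(eyeVelocity(mid$traces$anterior),
               0.5 * eyeVelocity(samples[[1]]$traces$anterior) +
               0.5 * eyeVelocity(samples[[2]]$traces$anterior),
               tolerance = 1e-12)
  # gains g1, g2 on a shared head profile blend linearly in the area ratio
  gA <- 0.6; gB <- 1.1
  sA <- list(id = "a", label = "CR",
             traces = lapply(setNames(nm = c("horizontal", "anterior",
                                             "posterior")),
                             function(s) pureGainTrace(gA, scc = s)))
  sB <- list(id = "b", label = "CR",
             traces = lapply(setNames(nm = c("horizontal", "anterior",
                                             "posterior")),
                             function(s) pureGainTrace(gB, scc = s)))
  augL <- augmentITS(list(sA, sB), 5, seed = 9)
  prov <- provenance(augL)
  for (k in which(prov$type == "ITS-blend")) {
    lam <- prov$weight[k]
    blend <- augmentedSamples(augL)[[k]]
    expect_equal(vorGain(blend$traces$posterior),
                 lam * gA + (1 - lam) * gB, tolerance = 1e-6)
    # pointwise between the parents
    lo <- pmin(eyeVelocity(sA$traces$posterior),
               eyeVelocity(sB$traces$posterior))
    hi <- pmax(eyeVelocity(sA$traces$posterior),
               eyeVelocity(sB$traces$posterior))
    bv <- eyeVelocity(blend$traces$posterior)
    expect_true(all(bv >= lo - 1e-12 & bv <= hi + 1e-12))
  }
  expect_error(augmentITS(list(sA), 3), "two minority")
})

test_that("every augmentation scheme balances 20 vs 44 exactly", {
  m <- makeMinority(20, list(c(5, 6, 7, 8)))
  samples <- representativeSamples(m$cohort, m$analyses)
  for (aug in list(augmentOS(samples, 44, seed = 2),
                   augmentEDE(m$cohort, m$analyses, 44),
                   augmentITS(samples, 44, seed = 2))) {
    expect_length(augmentedSamples(aug), 44)
  }
})

test_that("coherence analysis runs on augmented samples", {
  m <- makeMinority(2, list(c(5, 6, 7)))
  samples <- representativeSamples(m$cohort, m$analyses)
  aug <- augmentITS(samples, 3, seed = 4)
  s <- augmentedSamples(aug)[[3]]
  for (scc in names(s$traces)) {
    tr <- s$traces[[scc]]
    map <- mswc(headVelocity(tr), eyeVelocity(tr), samplingRate(tr))
    expect_s4_class(map, "CoherenceMap")
    expect_gte(map@coherentFrequency, 0)
  }
})
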