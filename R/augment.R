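#' @include features.R
NULL

#' Build representative classification samples from an analyzed cohort
#'
#' One sample per patient: the three representative repeats (one per SCC)
#' plus the outcome label collapsed to the classification target (CR vs
#' PR+NR).
#'
#' @param cohort list of \linkS4class{PatientRecord}.
#' @param analyses result of \code{\link{analyzeCohort}}.
#' @return list of samples; each is a list with \code{id}, \code{label}
#'   ("CR" or "PRNR") and \code{traces} (named list per SCC).
#' @export
representativeSamples <- function(cohort, analyses) {
  lapply(cohort, function(pat) {
    an <- analyses[[pat@patientId]]
    traces <- lapply(setNames(SCC_LEVELS, SCC_LEVELS), function(scc)
      pat@exams[[scc]][[an$scc[[scc]]$repIndex]])
    list(id = pat@patientId,
         label = if (pat@outcome == "CR") "CR" else "PRNR",
         traces = traces)
  })
}

newProvenance <- function(ids, type, parents = NA_character_,
                          weight = NA_real_) {
  if (length(ids) == 0L)
    return(data.frame(sample_id = character(0), type = character(0),
                      parents = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(sample_id = ids, type = type, parents = parents,
             weight = weight, stringsAsFactors = FALSE)
}

#' Minority-class augmentation by simple over-sampling (OS)
#'
#' Appends random-with-replacement copies of minority samples until the
#' minority reaches \code{targetN}.
#'
#' @param minority nonempty list of samples (see
#'   \code{\link{representativeSamples}}).
#' @param targetN target class size, >= length(minority).
#' @param seed seed for the copy draw.
#' @return an \linkS4class{AugmentedSet} (originals first, then copies).
#' @export
augmentOS <- function(minority, targetN, seed = NULL) {
  stopIfNot(length(minority) > 0, "minority set is empty")
  stopIfNot(targetN >= length(minority),
            "targetN is below the current minority size")
  nExtra <- targetN - length(minority)
  picks <- withSeed(seed, sample(length(minority), nExtra, replace = TRUE))
  copies <- lapply(seq_len(nExtra), function(k) {
    s <- minority[[picks[k]]]
    s$id <- sprintf("%s_os%d", s$id, k)
    s
  })
  prov <- rbind(
    newProvenance(vapply(minority, `[[`, character(1), "id"), "original"),
    newProvenance(vapply(copies, `[[`, character(1), "id"), "OS-copy",
                  parents = vapply(picks, function(i) minority[[i]]$id,
                                   character(1))))
  new("AugmentedSet", samples = c(minority, copies), provenance = prov)
}

#' Minority-class augmentation by extensive data extraction (EDE)
#'
#' Extra samples are real, non-representative repeats: for each minority
#' patient and SCC, the unused repeat whose coherent frequency is closest
#' to the representative's (ties to the earliest repeat). Patients are
#' cycled round-robin until \code{targetN} is reached; a patient with no
#' unused repeats left is skipped.
#'
#' @param minorityCohort list of minority-class
#'   \linkS4class{PatientRecord} (full repeat sets).
#' @param analyses result of \code{\link{analyzeCohort}} covering these
#'   patients.
#' @param targetN target class size.
#' @return an \linkS4class{AugmentedSet}; originals are the representative
#'   triplets, extras are extracted repeat triplets.
#' @export
augmentEDE <- function(minorityCohort, analyses, targetN) {
  stopIfNot(length(minorityCohort) > 0, "minority set is empty")
  stopIfNot(targetN >= length(minorityCohort),
            "targetN is below the current minority size")
  originals <- representativeSamples(minorityCohort, analyses)
  nExtra <- targetN - length(minorityCohort)
  # per patient per SCC: repeats ranked by |freq - representative freq|,
  # representative excluded, ties to the earlier repeat
  pool <- lapply(minorityCohort, function(pat) {
    an <- analyses[[pat@patientId]]
    lapply(setNames(SCC_LEVELS, SCC_LEVELS), function(scc) {
      a <- an$scc[[scc]]
      cand <- setdiff(seq_along(a$frequencies), a$repIndex)
      cand[order(abs(a$frequencies[cand] - a$repFrequency), cand)]
    })
  })
  used <- lapply(pool, function(p) lapply(p, function(x) 0L))
  extras <- list(); parents <- character()
  i <- 0L; idle <- 0L
  while (length(extras) < nExtra) {
    i <- i %% length(minorityCohort) + 1L
    depth <- used[[i]][["horizontal"]] + 1L
    if (all(vapply(SCC_LEVELS, function(scc)
          length(pool[[i]][[scc]]) >= depth, logical(1)))) {
      pat <- minorityCohort[[i]]
      traces <- lapply(setNames(SCC_LEVELS, SCC_LEVELS), function(scc)
        pat@exams[[scc]][[pool[[i]][[scc]][depth]]])
      k <- length(extras) + 1L
      extras[[k]] <- list(id = sprintf("%s_ede%d", pat@patientId, depth),
                          label = originals[[i]]$label, traces = traces)
      parents[k] <- pat@patientId
      for (scc in SCC_LEVELS) used[[i]][[scc]] <- depth
      idle <- 0L
    } else {
      idle <- idle + 1L
      if (idle >= length(minorityCohort))
        stop("no spare repeats left to extract", call. = FALSE)
    }
  }
  prov <- rbind(
    newProvenance(vapply(originals, `[[`, character(1), "id"), "original"),
    newProvenance(vapply(extras, `[[`, character(1), "id"), "EDE-extract",
                  parents = parents))
  new("AugmentedSet", samples = c(originals, extras), provenance = prov)
}

blendTraces <- function(a, b, lambda) {
  new("ImpulseTrace", time = a@time,
      headVelocity = lambda * a@headVelocity + (1 - lambda) * b@headVelocity,
      eyeVelocity = lambda * a@eyeVelocity + (1 - lambda) * b@eyeVelocity,
      samplingRate = a@samplingRate, onsetTime = a@onsetTime, scc = a@scc,
      trueParams = list(blend = TRUE, lambda = lambda))
}

#' Minority-class augmentation by interpolation of time series (ITS)
#'
#' Each synthetic sample is a per-sample convex combination
#' \eqn{\lambda a + (1-\lambda) b} of two distinct subjects' trace
#' triplets, with one \eqn{\lambda \sim U(0,1)} shared across the three
#' SCCs and both velocity channels. Parent pairs are drawn uniformly
#' without immediate repetition.
#'
#' @param minority list of >= 2 samples.
#' @param targetN target class size.
#' @param seed seed for the pair and weight draws.
#' @param lambda optional fixed interpolation weight(s) instead of uniform
#'   draws (recycled over the synthetic samples).
#' @return an \linkS4class{AugmentedSet}.
#' @export
augmentITS <- function(minority, targetN, seed = NULL, lambda = NULL) {
  stopIfNot(length(minority) >= 2, "ITS needs at least two minority subjects")
  stopIfNot(targetN >= length(minority),
            "targetN is below the current minority size")
  nExtra <- targetN - length(minority)
  blends <- withSeed(seed, {
    lastPair <- c(0L, 0L)
    lapply(seq_len(nExtra), function(k) {
      repeat {
        pair <- sort(sample(length(minority), 2))
        if (!identical(pair, lastPair) || length(minority) == 2) break
      }
      lastPair <<- pair
      lam <- if (is.null(lambda)) runif(1)
             else lambda[(k - 1) %% length(lambda) + 1]
      a <- minority[[pair[1]]]; b <- minority[[pair[2]]]
      traces <- lapply(setNames(SCC_LEVELS, SCC_LEVELS), function(scc)
        blendTraces(a$traces[[scc]], b$traces[[scc]], lam))
      list(id = sprintf("its%d_%s_%s", k, a$id, b$id), label = a$label,
           traces = traces, lambda = lam,
           parents = paste(a$id, b$id, sep = "+"))
    })
  })
  prov <- rbind(
    newProvenance(vapply(minority, `[[`, character(1), "id"), "original"),
    newProvenance(vapply(blends, `[[`, character(1), "id"), "ITS-blend",
                  parents = vapply(blends, `[[`, character(1), "parents"),
                  weight = vapply(blends, `[[`, numeric(1), "lambda")))
  blends <- lapply(blends, function(s) s[c("id", "label", "traces")])
  new("AugmentedSet", samples = c(minority, blends), provenance = prov)
}
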