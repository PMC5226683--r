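# Internal helpers shared across modules.

# Deterministic per-stage child seeds from one root seed, so each pipeline
# stage has an independent, reproducible stream. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    simulate = 11L, qc = 23L, tdt = 37L, enrichment = 41L,
    episcan = 53L, triocorr = 67L, qtl = 79L, universe = 97L,
    controls = 113L, misc = 131L
  )
  off <- offsets[[stage]]
  as.integer((abs(seed) * 7919 + off * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0/1 indicator matrix for dosage == v with NA treated as 0, double storage
# so crossprod() counts pairwise-complete individuals.
dosage_indicator <- function(G, v) {
  M <- (G == v)
  M[is.na(M)] <- FALSE
  storage.mode(M) <- "double"
  M
}

stop_if_not_cohort <- function(x) {
  if (!inherits(x, "trio_cohort"))
    stop("expected a 'trio_cohort' object (see simulate_trios() / read_ped_map())",
         call. = FALSE)
  invisible(x)
}
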