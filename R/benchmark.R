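BENCHMARK_METHODS <- c("mda_glm", "mda_glm_nd", "kr_glm", "kr_glm_nd",
                       "power_law_1", "power_law_2")

#' Score hydrodynamic-radius predictors on a benchmark set
#'
#' Runs the requested predictors over every record of a benchmark table
#' and scores each against the experimental radii with [error_stats()].
#' The simulation methods are: `mda_glm` (minimum dissipation estimate on
#' the annotated globule-linker chain), `kr_glm` (simplified
#' Kirkwood-Riseman on the same ensembles), and their `_nd` variants in
#' which the whole chain is treated as disordered regardless of
#' annotation ("no domain information"). `power_law_1` and `power_law_2`
#' are the fixed- and free-exponent [fit_power_law()] baselines, scored
#' under leave-one-out cross-validation with the matching number of
#' fitting parameters (1 and 2; the simulation methods have 0).
#'
#' Records whose sequence or annotation cannot be resolved are excluded
#' with a warning and listed in the result.
#'
#' @param records Data frame from [read_benchmark_csv()].
#' @param methods Subset of
#'   `c("mda_glm", "mda_glm_nd", "kr_glm", "kr_glm_nd", "power_law_1",
#'   "power_law_2")`.
#' @param n Ensemble size per protein.
#' @param seed Base seed; record k uses `seed + k`.
#' @param params A [glm_params()].
#' @return An object of class `"benchmark_result"`: list with `metrics`
#'   (one [error_stats()] row per method), `per_protein` (predictions per
#'   record and method) and `failed` (ids of excluded records).
#' @export
run_benchmark <- function(records, methods = BENCHMARK_METHODS, n = 100L,
                          seed = 0L, params = glm_params()) {
  if (length(methods)) methods <- match.arg(methods, BENCHMARK_METHODS,
                                            several.ok = TRUE)
  if (length(methods) == 0L || nrow(records) == 0L)
    return(structure(list(metrics = NULL, per_protein = NULL,
                          failed = character(0)),
                     class = "benchmark_result"))
  sim_methods <- intersect(methods, c("mda_glm", "kr_glm", "mda_glm_nd", "kr_glm_nd"))
  need_glm <- any(sim_methods %in% c("mda_glm", "kr_glm"))
  need_nd <- any(sim_methods %in% c("mda_glm_nd", "kr_glm_nd"))

  per <- data.frame(id = records$id, name = records$name,
                    n_residues = records$n_residues,
                    experimental_rh_A = records$experimental_rh_A,
                    stringsAsFactors = FALSE)
  for (m in methods) per[[m]] <- NA_real_
  failed <- character(0)

  if (length(sim_methods)) {
    for (k in seq_len(nrow(records))) {
      rec <- records[k, ]
      pred <- tryCatch(
        predict_record(rec, need_glm, need_nd, n, seed + k, params),
        error = function(e) {
          warning(sprintf("benchmark record '%s' skipped: %s",
                          rec$id, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(pred)) {
        failed <- c(failed, as.character(rec$id))
        next
      }
      for (m in sim_methods) per[[m]][k] <- pred[[m]]
    }
  }
  if ("power_law_1" %in% methods)
    per$power_law_1 <- fit_power_law(records$n_residues,
                                     records$experimental_rh_A,
                                     n_params = 1L)$loo_predictions
  if ("power_law_2" %in% methods)
    per$power_law_2 <- fit_power_law(records$n_residues,
                                     records$experimental_rh_A,
                                     n_params = 2L)$loo_predictions

  n_fp_of <- c(mda_glm = 0L, mda_glm_nd = 0L, kr_glm = 0L, kr_glm_nd = 0L,
               power_law_1 = 1L, power_law_2 = 2L)
  metrics <- do.call(rbind, lapply(methods, function(m) {
    ok <- is.finite(per[[m]])
    stats_row <- error_stats(per[[m]][ok], per$experimental_rh_A[ok],
                             n_fp = n_fp_of[[m]])
    cbind(data.frame(model = m, stringsAsFactors = FALSE), stats_row)
  }))
  class(metrics) <- "data.frame"
  structure(list(metrics = metrics, per_protein = per, failed = failed),
            class = "benchmark_result")
}

# One record: resolve sequence + annotation files, run the sampler once
# per annotation mode, return all four simulation predictions.
predict_record <- function(rec, need_glm, need_nd, n, seed, params) {
  seqs <- read_fasta(rec$fasta_path)
  sequence <- if (!is.na(rec$id) && rec$id %in% names(seqs))
    seqs[[as.character(rec$id)]] else seqs[[1]]
  if (is.finite(rec$n_residues) && nchar(sequence) != rec$n_residues)
    stop(sprintf("sequence length %d disagrees with n_residues %d",
                 nchar(sequence), rec$n_residues))
  out <- list()
  if (need_glm) {
    ann_path <- rec$annotation_path
    fit <- if (grepl("\\.tsv$", ann_path)) {
      glm_rh(sequence, domains = read_domain_tsv(ann_path), params = params,
             n_conformers = n, seed = seed)
    } else {
      track <- read_disorder_track(ann_path, sequence = sequence)
      glm_rh(track, params = params, n_conformers = n, seed = seed)
    }
    out$mda_glm <- fit$rh_mda
    out$kr_glm <- fit$rh_kirkwood_simplified
  }
  if (need_nd) {
    fit <- glm_rh(sequence, no_domains = TRUE, params = params,
                  n_conformers = n, seed = seed)
    out$mda_glm_nd <- fit$rh_mda
    out$kr_glm_nd <- fit$rh_kirkwood_simplified
  }
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  if (is.null(x$metrics)) {
    cat("Empty benchmark result\n")
    return(invisible(x))
  }
  cat("Benchmark error statistics:\n")
  print(format(x$metrics, digits = 4), row.names = FALSE)
  if (length(x$failed))
    cat(sprintf("Excluded records: %s\n", paste(x$failed, collapse = ", ")))
  invisible(x)
}
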