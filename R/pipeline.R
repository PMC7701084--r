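# FNV-1a hash of a character scalar; used only to fingerprint run
# configurations in the manifest.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor the low 16 bits (doubles exceed bitwXor's integer range)
    lo <- h %% 65536
    h <- h - lo + bitwXor(lo, b)
    # 32-bit FNV prime multiplication (16777619 = 403 + 2^24), kept exact in
    # double precision by shifting only the low byte into the high word
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full monitoring analysis over a cohort
#'
#' Executes, in order: per-patient summarisation, the patient-level
#' association scan (ANOVA / regression of mean log10 TTV on fixed
#' covariates), the repeated-measures correlation scan (within-patient
#' permutation tests over the monthly metric covariates), and the four
#' random-intercept logistic event models. Each stage is isolated: a stage
#' error is recorded in the manifest under the stage name and the remaining
#' independent stages still run. Outputs are the three result CSVs plus a
#' JSON manifest recording seed, permutation count, package version and a
#' configuration fingerprint; identical cohort + configuration yields
#' byte-identical outputs.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param out_dir output directory.
#' @param n_permutations permutation iterations per correlation variable
#'   (study default 10000).
#' @param seed integer seed for the permutation tests (model fitting is
#'   deterministic).
#' @param min_pairs minimum complete pairs per patient in the correlation
#'   stage.
#' @param quad quadrature specification for the event models.
#' @param mismatch_as treatment of the HLA mismatch count in the association
#'   scan.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(cohort, out_dir, n_permutations = 10000, seed = 1,
                         min_pairs = 3, quad = quad_spec(),
                         mismatch_as = "continuous") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  validate_cohort(cohort)

  stage <- function(fn) {
    tryCatch(list(ok = TRUE, value = fn()),
             error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  }

  assoc <- stage(function() run_association_scan(cohort, mismatch_as))
  corr <- stage(function() run_correlation_scan(cohort, n_permutations,
                                                seed, min_pairs))
  events <- stage(function() run_event_models(cohort, quad))

  keep_fitted <- function(x) Filter(function(r) !inherits(r, "ttv_skipped"), x)
  results <- c(
    if (assoc$ok) keep_fitted(assoc$value) else list(),
    if (corr$ok) keep_fitted(corr$value) else list(),
    if (events$ok) keep_fitted(events$value) else list()
  )
  if (length(results) > 0) write_results(unname(results), out_dir)

  stage_status <- function(s, nm) {
    if (!s$ok) return(paste0("error: ", s$value))
    skipped <- names(Filter(function(r) inherits(r, "ttv_skipped"), s$value))
    if (length(skipped) > 0) paste0("ok (skipped: ",
                                    paste(skipped, collapse = ", "), ")")
    else "ok"
  }
  cfg_txt <- paste(deparse(list(n_permutations = n_permutations, seed = seed,
                                min_pairs = min_pairs,
                                n_nodes = quad$n_nodes,
                                adaptive = quad$adaptive,
                                mismatch_as = mismatch_as)), collapse = "")
  manifest <- list(
    package = "ttvload",
    version = as.character(utils::packageVersion("ttvload")),
    seed = as.integer(seed),
    n_permutations = as.integer(n_permutations),
    min_pairs = as.integer(min_pairs),
    quadrature_nodes = quad$n_nodes,
    config_hash = fnv1a_hash(cfg_txt),
    n_patients = nrow(cohort$patients),
    n_visits = nrow(cohort$visits),
    stages = list(associations = stage_status(assoc),
                  correlations = stage_status(corr),
                  event_models = stage_status(events))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(associations = if (assoc$ok) assoc$value else NULL,
                 correlations = if (corr$ok) corr$value else NULL,
                 event_models = if (events$ok) events$value else NULL,
                 manifest = manifest))
}
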