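#' End-to-end generator benchmark
#'
#' The package's full comparison recipe: take (or simulate) a structured
#' haplotype dataset, split it 3:1 into training and test haplotypes, train
#' the requested generative models on the training part, generate one
#' artificial set of `n_generate` haplotypes per model, and evaluate every
#' artificial set against the training data with the complete metrics suite
#' (privacy loss uses the held-out test part).  A `"test"` pseudo-model — the
#' held-out haplotypes treated as perfectly generated data — is included as
#' the reference for the best achievable scores.
#'
#' @param M a [haplotype_matrix()]; `NULL` (default) simulates the desk-scale
#'   two-population dataset with [simulate_structured()] defaults.
#' @param models character subset of
#'   `c("bernoulli", "markov", "gan", "rbm", "test")`.
#' @param n_generate artificial haplotypes per model; defaults to the
#'   training-set size.
#' @param markov_window Markov context window.
#' @param gan_epochs,rbm_epochs,rbm_hidden training lengths and RBM width.
#' @param gan_restarts independent GAN trainings; the run whose held-out
#'   AA_TS probe comes closest to the ideal 0.5 is kept (adversarial
#'   training is run-to-run unstable, so restart selection on the
#'   validation probe is part of the recipe).
#' @param rbm_gibbs Gibbs sweeps for RBM sampling.
#' @param seed master seed; every stage derives its own seed from it, so the
#'   whole benchmark re-runs bitwise from the manifest.
#' @param out_dir optional directory: writes `manifest.json` (when jsonlite
#'   is available), `comparison.tsv` and the generated hapt files.
#' @return object of class `ag_benchmark`: list with `reports` (one
#'   [evaluate_pair()] report per model), `comparison` (tibble, one row per
#'   model with the scalar metrics, ordered by 2-D Wasserstein distance),
#'   `fits`, `data` (`train`/`test`) and `manifest`.
#' @export
run_benchmark <- function(M = NULL,
                          models = c("bernoulli", "markov", "gan", "rbm",
                                     "test"),
                          n_generate = NULL, markov_window = 10L,
                          gan_epochs = 3000L, gan_restarts = 3L,
                          rbm_epochs = 250L,
                          rbm_hidden = 100L, rbm_gibbs = 100L,
                          seed = 1L, out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(M)) M <- simulate_structured(seed = seed)
  M <- validate_haplotype_matrix(M)
  split <- split_train_test(M, ratio = 0.75, seed = seed)
  train <- split$train; test <- split$test
  if (is.null(n_generate)) n_generate <- n_haplotypes(train)
  stage_seed <- function(k) seed + k  # fixed offsets: manifest-reproducible
  fits <- list(); ags <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("benchmark stage '%s' failed (seed %d): %s", name, seed,
                   conditionMessage(e)), call. = FALSE))
  }
  if ("bernoulli" %in% models) run_stage("bernoulli", {
    fits$bernoulli <- fit_bernoulli(train)
    ags$bernoulli <- generate_bernoulli(fits$bernoulli, n_generate,
                                         seed = stage_seed(11L))
  })
  if ("markov" %in% models) run_stage("markov", {
    fits$markov <- fit_markov(train, window = markov_window)
    ags$markov <- generate_markov(fits$markov, n_generate,
                                   seed = stage_seed(12L))
  })
  if ("gan" %in% models) run_stage("gan", {
    runs <- lapply(seq_len(gan_restarts), function(r)
      train_gan(train, epochs = gan_epochs, validation = test,
                keep_best = TRUE, seed = stage_seed(13L) + 100L * (r - 1L)))
    probe_gap <- vapply(runs, function(f)
      min(abs(f$history$aats_probe - 0.5), na.rm = TRUE), numeric(1))
    fits$gan <- runs[[which.min(probe_gap)]]
    ags$gan <- generate_gan(fits$gan, n_generate, seed = stage_seed(14L))
  })
  if ("rbm" %in% models) run_stage("rbm", {
    fits$rbm <- train_rbm(train, n_hidden = rbm_hidden, epochs = rbm_epochs,
                           seed = stage_seed(15L))
    ags$rbm <- sample_rbm(fits$rbm, n_generate, init = "train_set",
                           init_data = train, n_gibbs = rbm_gibbs,
                           seed = stage_seed(16L))
  })
  if ("test" %in% models) ags$test <- test
  reports <- lapply(names(ags), function(nm)
    run_stage(paste0("evaluate_", nm),
              evaluate_pair(train, ags[[nm]], train = train, test = test,
                            seed = stage_seed(20L))))
  names(reports) <- names(ags)
  comparison <- dplyr::bind_rows(lapply(names(reports), function(nm)
    dplyr::bind_cols(tibble::tibble(model = nm), reports[[nm]]$summary)))
  comparison <- dplyr::arrange(comparison, .data$wasserstein_pca2d)
  manifest <- list(package_version = as.character(utils::packageVersion("haplogen")),
                   seed = seed, models = models, n_generate = n_generate,
                   n_train = n_haplotypes(train), n_test = n_haplotypes(test),
                   n_snps = ncol(train), markov_window = markov_window,
                   gan_epochs = gan_epochs, gan_restarts = gan_restarts,
                   rbm_epochs = rbm_epochs,
                   rbm_hidden = rbm_hidden, rbm_gibbs = rbm_gibbs)
  out <- structure(list(reports = reports, comparison = comparison,
                        fits = fits, data = list(train = train, test = test),
                        manifest = manifest),
                   class = "ag_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(ags))
      write_hapt(ags[[nm]], file.path(out_dir, paste0("ag_", nm, ".hapt")))
    write_hapt(train, file.path(out_dir, "train.hapt"))
    write_hapt(test, file.path(out_dir, "test.hapt"))
  }
  out
}

#' @export
print.ag_benchmark <- function(x, ...) {
  cat(sprintf("<ag_benchmark: %d train / %d test haplotypes, %d SNPs, seed %d>\n",
              x$manifest$n_train, x$manifest$n_test, x$manifest$n_snps,
              x$manifest$seed))
  print(as.data.frame(x$comparison), row.names = FALSE, digits = 3)
  invisible(x)
}
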