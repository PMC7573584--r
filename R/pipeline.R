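default_study_config <- function() {
  list(priors = "proportional",       # LDA priors
       n_permutations = 500,          # allometry permutations
       boot_reps = 200,               # morphometric NJ bootstrap replicates
       lasec_iterations = 100,        # LaSEC sampling iterations
       min_sites = 3,                 # design check threshold
       trim = 550,                    # COI trim length (bp)
       run_model_test = TRUE,
       phylo_boot = 100,              # ML bootstrap replicates
       run_lasec = TRUE,
       run_trees = TRUE,
       seed = 1)
}

#' Run the full wing-morphometrics study analogue
#'
#' Executes the complete analysis chain on a landmark dataset:
#' superimposition, centroid-size ANOVA with Bonferroni pairwise tests,
#' allometry permutation test, genus- and species-rank LDA with
#' leave-one-out cross-validation, canonical variate analysis with a
#' bootstrapped neighbor-joining tree of Mahalanobis distances, per-species
#' shape disparity, observer-error comparison (when replicates are given),
#' the landmark sampling evaluation curve, and -- when sequences are given
#' -- COI model selection, maximum-likelihood tree and bootstrap. Stage
#' failures are caught and recorded; later independent stages still run.
#' With a fixed `config$seed` the report is reproducible.
#'
#' @param landmarks a [landmark_dataset()]
#' @param replicates optional [landmark_dataset()] of observer replicates
#' @param sequences optional character alignment matrix (taxa x sites)
#' @param config named list overriding entries of the default configuration
#'   (priors, n_permutations, boot_reps, lasec_iterations, min_sites, trim,
#'   run_model_test, phylo_boot, run_lasec, run_trees, seed)
#' @return object of class `study_report`; element `errors` lists failed
#'   stages, `metadata` echoes the configuration in effect
#' @export
run_study <- function(landmarks, replicates = NULL, sequences = NULL,
                      config = list()) {
  stopifnot(inherits(landmarks, "landmark_dataset"))
  cfg <- utils::modifyList(default_study_config(), config)
  report <- list(metadata = list(config = cfg,
                                 n_specimens = n_specimens(landmarks),
                                 k = landmarks$k))
  errors <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    report[[name]] <<- res
    invisible(res)
  }

  stage("validation", validate_dataset(landmarks, cfg$min_sites))
  gpa <- stage("gpa", generalized_procrustes(landmarks))
  if (is.null(gpa)) {
    report$errors <- errors
    return(structure(report, class = "study_report"))
  }
  shapes <- tangent_projection(gpa)
  sizes <- gpa$centroid_sizes
  species <- gpa$meta$species
  genus <- gpa$meta$genus
  genus_map <- stats::setNames(genus, species)[!duplicated(species)]

  stage("size_anova", anova_centroid_size(sizes, species))
  stage("size_pairwise", pairwise_t_bonferroni(sizes, species))
  stage("allometry", allometry_test(shapes, sizes,
                                    n_permutations = cfg$n_permutations,
                                    seed = cfg$seed))
  sp_conf <- stage("species_loocv",
                   loocv_confusion(shapes, species, priors = cfg$priors,
                                   rank = "species"))
  stage("genus_loocv", loocv_confusion(shapes, genus, priors = cfg$priors,
                                       rank = "genus"))
  if (!is.null(sp_conf))
    stage("species_collapsed_to_genus",
          collapse_to_genus(sp_conf, genus_map))
  stage("cva", cva(shapes, species))
  if (isTRUE(cfg$run_trees))
    stage("nj_tree", {
      tr <- bootstrap_support(shapes, species, n_reps = cfg$boot_reps,
                              seed = cfg$seed)
      list(newick = write_newick(tr),
           n_effective = attr(tr, "n_effective"))
    })
  stage("disparity", shape_variance(shapes, species))
  if (!is.null(replicates))
    stage("observer_error", observer_error_report(landmarks, replicates))
  if (isTRUE(cfg$run_lasec))
    stage("lasec", lasec_curve(landmarks,
                               n_iterations = cfg$lasec_iterations,
                               seed = cfg$seed))
  if (!is.null(sequences))
    stage("phylo", {
      aln <- trim_alignment(sequences, cfg$trim)
      mt <- if (isTRUE(cfg$run_model_test)) model_test(aln) else NULL
      best <- if (!is.null(mt)) attr(mt, "best") else "HKY85+G"
      fam <- sub("\\+G$", "", best)
      model <- substitution_model(
        fam, kappa = 2,
        base_freq = if (fam == "HKY85") empirical_base_freq(aln) else NULL,
        gamma = grepl("\\+G$", best), alpha = 0.5)
      fit <- ml_search(aln, model, optimize_params = TRUE)
      btree <- bootstrap_ml(aln, fit$model, n_reps = cfg$phylo_boot,
                            seed = cfg$seed, full_fit = fit)
      list(model_table = if (!is.null(mt)) as.data.frame(mt) else NULL,
           best_model = best, logLik = fit$logLik, aic = fit$AIC,
           newick = write_newick(btree))
    })
  report$errors <- errors
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Wing morphometrics study report\n")
  cat("  specimens: ", x$metadata$n_specimens, ", landmarks: ",
      x$metadata$k, "\n", sep = "")
  if (!is.null(x$size_anova))
    cat(sprintf("  centroid size ANOVA: F = %.2f (df %d, %d), p = %.3g\n",
                x$size_anova$f_statistic, x$size_anova$df_between,
                x$size_anova$df_within, x$size_anova$p_value))
  if (!is.null(x$allometry))
    cat(sprintf("  allometry: R2 = %.2f%%, p = %.4g\n",
                100 * x$allometry$r_squared, x$allometry$p_value))
  if (!is.null(x$genus_loocv))
    cat(sprintf("  genus LOOCV accuracy: %.1f%%\n",
                100 * x$genus_loocv$accuracy))
  if (!is.null(x$species_loocv))
    cat(sprintf("  species LOOCV accuracy: %.1f%%\n",
                100 * x$species_loocv$accuracy))
  if (!is.null(x$disparity))
    cat(sprintf("  mean per-species shape variance: %.5g\n",
                x$disparity$grand_mean_variance))
  if (!is.null(x$observer_error))
    cat(sprintf("  observer vs species variance: %.5g vs %.5g (ratio %.2f)\n",
                x$observer_error$observer_variance,
                x$observer_error$species_variance, x$observer_error$ratio))
  if (!is.null(x$phylo))
    cat("  COI best model: ", x$phylo$best_model, ", lnL = ",
        sprintf("%.2f", x$phylo$logLik), "\n", sep = "")
  if (length(x$errors))
    cat("  FAILED stages: ", paste(names(x$errors), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

report_to_list <- function(x) {
  out <- list(metadata = x$metadata)
  num <- function(v) unclass(v)
  if (!is.null(x$validation))
    out$validation <- list(species_table = x$validation$species_table,
                           flagged_species = x$validation$flagged_species,
                           ok = x$validation$ok)
  if (!is.null(x$size_anova)) out$size_anova <- x$size_anova
  if (!is.null(x$size_pairwise))
    out$size_pairwise_bonferroni <- as.data.frame(x$size_pairwise)
  if (!is.null(x$allometry))
    out$allometry <- x$allometry[c("r_squared", "f_statistic", "p_value",
                                   "n_permutations")]
  for (nm in c("species_loocv", "genus_loocv", "species_collapsed_to_genus"))
    if (!is.null(x[[nm]]))
      out[[nm]] <- list(counts = as.data.frame(unclass(x[[nm]]$counts)),
                        accuracy = x[[nm]]$accuracy,
                        percentages = as.data.frame(unclass(
                          x[[nm]]$percentages)))
  if (!is.null(x$cva))
    out$cva <- list(mahalanobis = as.data.frame(x$cva$mahalanobis),
                    eigenvalues = x$cva$eigenvalues)
  if (!is.null(x$nj_tree)) out$nj_tree <- x$nj_tree
  if (!is.null(x$disparity))
    out$disparity <- list(
      per_group_variance = as.list(x$disparity$per_group_variance),
      grand_mean_variance = x$disparity$grand_mean_variance)
  if (!is.null(x$observer_error))
    out$observer_error <- x$observer_error[c("observer_variance",
                                             "species_variance", "ratio",
                                             "n_repeated_specimens")]
  if (!is.null(x$lasec)) out$lasec <- list(curve = x$lasec$curve)
  if (!is.null(x$phylo)) out$phylo <- x$phylo
  out$errors <- x$errors
  out
}

#' Serialize a study report to JSON (+ CSV side files)
#'
#' @param report a `study_report`
#' @param dir output directory (created if absent)
#' @return invisibly, the path of the JSON file
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in c("species_loocv", "genus_loocv"))
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]]$counts,
                       file.path(dir, paste0(nm, "_counts.csv")))
  if (!is.null(report$cva))
    utils::write.csv(report$cva$mahalanobis,
                     file.path(dir, "mahalanobis.csv"))
  if (!is.null(report$lasec))
    utils::write.csv(report$lasec$curve, file.path(dir, "lasec.csv"),
                     row.names = FALSE)
  if (!is.null(report$nj_tree))
    writeLines(report$nj_tree$newick, file.path(dir, "nj_tree.nwk"))
  if (!is.null(report$phylo) && !is.null(report$phylo$newick))
    writeLines(report$phylo$newick, file.path(dir, "ml_tree.nwk"))
  invisible(path)
}
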