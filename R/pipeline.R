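#' Default pipeline configuration
#'
#' A complete, explicit configuration for [run_pipeline()]: a demo-scale
#' cohort (400 families in the discovery-sample proportions, 96 vertices in
#' 12 planted blocks), moment-estimator genetic correlations, 12-cluster
#' FANNY parcellation and a spline association scan at FWER 5%. Every
#' default is spelled out so the run report echoes the full parameter set.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    structure = list(n_mz_pairs = 97L, n_dz_pairs = 137L, n_sib_pairs = 31L,
                     n_mz_trios = 9L, n_dz_trios = 13L, n_sib_trios = 0L,
                     n_singletons = 113L),
    arch = list(n_vertices = 96L, n_blocks = 12L, within_block_rg = 0.8,
                between_block_rg = 0, h2_vertex = 0.55, h2_score = 0.28,
                rg_score_target = 0.1, target_block = 6L,
                spline_effect = c(0, 0, -0.10), score_tail = 0.8),
    clustering = list(k = 12L, k_range = NULL, memb_exp = 2,
                      plateau_frac = 0.02, estimator = "moment"),
    association = list(fwer = 0.05, winsor_k = 4),
    twin = list(n_starts = 3))
}

check_config_keys <- function(config, reference, path = "config") {
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown))
    stop("unknown ", path, " keys: ", paste(unknown, collapse = ", "))
  for (nm in names(config))
    if (is.list(reference[[nm]]) && !is.null(names(reference[[nm]])) &&
        is.list(config[[nm]]))
      check_config_keys(config[[nm]], reference[[nm]],
                        paste0(path, "$", nm))
  invisible(TRUE)
}

merge_config <- function(user, defaults) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full endophenotype-discovery pipeline
#'
#' Orchestrates simulate -> residualise -> genetic correlations ->
#' parcellate -> cluster means -> spline association scan -> bivariate
#' AE decomposition of every hit, as one reproducible run. Stage
#' artifacts (TSV tables, JSON report) are written under `out_dir` when
#' given, so any stage can be inspected or re-run on real data dropped in
#' at the residualise stage. A failure in any stage aborts with the stage
#' name after persisting the artifacts produced so far.
#'
#' @param config a configuration list (see [default_pipeline_config()]),
#'   or a path to a YAML file with the same structure; omitted entries
#'   take their defaults, unknown keys are rejected.
#' @param out_dir optional output directory.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  check_config_keys(config, defaults)
  config <- merge_config(config, defaults)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("endotwin")),
                 r_version = R.version.string,
                 config = config, stages = list())
  t_all <- proc.time()[3]
  persist <- function(name, obj, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    writer(obj, file.path(out_dir, name))
  }
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    res
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646L, 5)

  cohort <- run_stage("simulate", {
    co <- simulate_cohort(do.call(family_structure_spec, config$structure),
                          do.call(architecture_spec, config$arch),
                          seed = stage_seeds[1])
    if (!is.null(out_dir)) write_cohort(co, out_dir)
    co
  })
  fams <- cohort$individuals
  covars <- data.frame(sex = fams$sex, age_scan = fams$age_scan,
                       age_score = fams$age_score, wave = fams$wave,
                       acquisition = fams$acquisition,
                       global_mean = rowMeans(cohort$vertices))
  resid <- run_stage("residualize",
                     residualize(cohort$vertices, covars))
  G <- run_stage("genetic_correlation", {
    g <- pairwise_genetic_correlations(resid, fams,
                                       estimator = config$clustering$estimator)
    persist("genetic_correlation.tsv",
            data.frame(vertex = g$vertex_ids, g$rg, check.names = FALSE),
            write_tsv)
    g
  })
  parcel <- run_stage("parcellate", {
    D <- to_dissimilarity(G)
    sel <- NULL
    k <- config$clustering$k
    if (!is.null(config$clustering$k_range)) {
      sel <- select_k(D, config$clustering$k_range,
                      plateau_frac = config$clustering$plateau_frac,
                      memb_exp = config$clustering$memb_exp)
      k <- sel$recommended_k
      persist("silhouette_curve.tsv", sel$curve, write_tsv)
    }
    cl <- fanny_cluster(D, k, memb_exp = config$clustering$memb_exp)
    sil <- silhouette_mean(cl$clustering, D)
    persist("clusters.tsv",
            data.frame(vertex = G$vertex_ids, cluster = cl$clustering,
                       top_membership = apply(cl$membership, 1, max),
                       silhouette = sil$widths),
            write_tsv)
    list(D = D, selection = sel, clustering = cl, silhouette = sil, k = k)
  })
  clusters <- run_stage("cluster_means",
                        cluster_mean_phenotypes(resid,
                                                parcel$clustering$clustering))
  scan <- run_stage("associate", {
    sc <- run_association_scan(clusters, cohort$score, covars,
                               kinship = fams,
                               fwer = config$association$fwer,
                               winsor_k = config$association$winsor_k)
    persist("association_scan.tsv", sc$table, write_tsv)
    sc
  })
  decomposition <- run_stage("bivariate_decomposition", {
    hits <- unique(scan$hits$phenotype)
    ws <- winsorise(cohort$score, k_sd = config$association$winsor_k)
    rows <- lapply(hits, function(ph) {
      Y <- cbind(clusters[, ph], as.numeric(ws))
      full <- fit_bivariate_ae(Y, fams, n_starts = config$twin$n_starts)
      red <- fit_bivariate_ae(Y, fams, "rg_zero",
                              n_starts = config$twin$n_starts)
      lr <- suppressWarnings(lrt(full, red, df = 1))
      data.frame(phenotype = ph, h2_cluster = full$h2[1],
                 h2_score = full$h2[2], rg = full$rg, re = full$re,
                 rp = full$rp, lrt_stat = lr$statistic, lrt_p = lr$p)
    })
    dec <- if (length(rows)) do.call(rbind, rows) else
      data.frame(phenotype = character(0), h2_cluster = numeric(0),
                 h2_score = numeric(0), rg = numeric(0), re = numeric(0),
                 rp = numeric(0), lrt_stat = numeric(0), lrt_p = numeric(0))
    persist("bivariate_decomposition.tsv", dec, write_tsv)
    dec
  })
  report$seed_substreams <- stage_seeds
  report$silhouette <- parcel$silhouette$mean
  report$k <- parcel$k
  report$selection <- if (!is.null(parcel$selection))
    parcel$selection$curve else NULL
  report$multiple_testing <- unclass(scan$plan)
  report$n_winsorised <- scan$n_winsorised
  report$hits <- scan$hits
  report$decomposition <- decomposition
  report$scan_table <- scan$table
  report$cluster_sizes <- tabulate(parcel$clustering$clustering, parcel$k)
  report$total_seconds <- round(proc.time()[3] - t_all, 3)
  if (!is.null(out_dir)) {
    rep_json <- report
    rep_json$hits <- NULL; rep_json$scan_table <- NULL
    rep_json$decomposition <- NULL
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report$cohort <- cohort
  report$clusters <- clusters
  report$parcel <- parcel
  report$scan <- scan
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  cohort: %d individuals, %d vertices, k = %d clusters (mean silhouette %.3f)\n",
              nrow(x$cohort$individuals), ncol(x$cohort$vertices), x$k,
              x$silhouette))
  cat(sprintf("  multiple testing: Meff %.1f -> %d tests, Sidak threshold %.3g\n",
              x$multiple_testing$meff, x$multiple_testing$n_tests,
              x$multiple_testing$threshold_sidak))
  if (nrow(x$hits)) {
    cat("  hits:\n"); print(x$hits, row.names = FALSE, digits = 4)
    cat("  genetic/environmental decomposition of hits:\n")
    print(x$decomposition, row.names = FALSE, digits = 4)
  } else cat("  no significant associations\n")
  cat(sprintf("  total time: %.1f s\n", x$total_seconds))
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Diagnostics-only checks for user-supplied tables: id alignment between
#' the individual table, phenotype matrix and score; missingness summary;
#' relationship-code consistency within families; kinship symmetry. Never
#' raises an error — returns a data frame of findings so problems can be
#' fixed before [run_pipeline()] or the per-stage functions are called.
#'
#' @param individuals individual table (`individual_id`, `family_id`,
#'   `rel`).
#' @param phenotypes optional phenotype matrix with individual rownames.
#' @param score optional data frame with `individual_id` and `score`
#'   columns (or a bare numeric vector of length `nrow(individuals)`).
#' @param kinship optional square kinship matrix.
#' @return data frame with columns `level` (`ok`/`warning`/`error`),
#'   `check`, `message`.
#' @export
validate_inputs <- function(individuals, phenotypes = NULL, score = NULL,
                            kinship = NULL) {
  out <- list()
  add <- function(level, check, message)
    out[[length(out) + 1L]] <<- data.frame(level = level, check = check,
                                           message = message)
  ids <- as.character(individuals$individual_id)
  if (anyDuplicated(ids))
    add("error", "ids", paste("duplicated individual ids:",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  else add("ok", "ids", "individual ids unique")
  for (rows in split(seq_len(nrow(individuals)), individuals$family_id)) {
    rel <- individuals$rel[rows]
    fid <- individuals$family_id[rows[1]]
    if (length(rows) > 3L)
      add("error", "family_size",
          paste("family", fid, "has", length(rows), "members (max 3)"))
    if (sum(rel == "MZ") == 1L)
      add("error", "relationship",
          paste("family", fid, "has a lone MZ-coded member"))
    if (length(rows) > 1L && any(rel == "SINGLETON"))
      add("error", "relationship",
          paste("family", fid, "mixes SINGLETON with other codes"))
  }
  if (!is.null(phenotypes)) {
    pid <- rownames(phenotypes)
    if (is.null(pid))
      add("warning", "phenotypes", "phenotype matrix has no rownames")
    else {
      miss <- setdiff(ids, pid)
      extra <- setdiff(pid, ids)
      if (length(miss))
        add("error", "phenotypes",
            paste("ids missing from phenotypes:",
                  paste(miss, collapse = ", ")))
      if (length(extra))
        add("error", "phenotypes",
            paste("phenotype ids not in individual table:",
                  paste(extra, collapse = ", ")))
      if (!length(miss) && !length(extra))
        add("ok", "phenotypes", "phenotype ids aligned")
    }
    nmiss <- sum(is.na(phenotypes))
    add(if (nmiss) "warning" else "ok", "missingness",
        paste(nmiss, "missing phenotype values"))
  }
  if (!is.null(score)) {
    if (is.data.frame(score)) {
      miss <- setdiff(ids, as.character(score$individual_id))
      if (length(miss))
        add("error", "score", paste("ids missing from score table:",
                                    paste(miss, collapse = ", ")))
      else add("ok", "score", "score ids aligned")
    } else if (length(score) != length(ids)) {
      add("error", "score", "score length does not match individual table")
    } else add("ok", "score", "score aligned by position")
  }
  if (!is.null(kinship)) {
    kin <- as.matrix(kinship)
    if (nrow(kin) != ncol(kin))
      add("error", "kinship", "kinship matrix is not square")
    else if (!isTRUE(all.equal(kin, t(kin), tolerance = 1e-8)))
      add("error", "kinship", "kinship matrix is not symmetric")
    else add("ok", "kinship", "kinship matrix symmetric")
  }
  do.call(rbind, out)
}
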