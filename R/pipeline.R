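# End-to-end pipeline: MA maps -> similarity -> clustering & K selection ->
# per-MAG ALE with cluster-FWE -> phenotype report, with seeding, logging
# and a provenance manifest.

pipeline_defaults <- function() {
  list(
    foci = NULL,                 # path to foci table (NULL -> simulate)
    metadata = NULL,             # path to metadata table
    mask = "ellipsoid",          # NIfTI path or "ellipsoid"
    out_dir = "magale_run",
    fwhm_subject_mm = 11.6,
    fwhm_template_mm = 5.7,
    truncation_radius_sd = 3.5,
    sample_size = "cases",
    k_range = c(2, 15),
    subsample_fraction = 0.9,
    subsample_iterations = 5000,
    k_override = NULL,
    min_group_size = 10,
    alpha_voxel = 0.001,
    alpha_cluster = 0.05,
    n_permutations = 5000,
    connectivity = 26,
    voxel_null = "histogram",
    tal_method = "lancaster",
    seed = 1
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON config file path or an R list; unknown keys are rejected
#' by name, missing keys take the documented defaults, and thresholds are
#' range-checked.
#'
#' @param config path to a JSON file, or a named list (possibly empty).
#' @return normalized `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (key in c("alpha_voxel", "alpha_cluster"))
    if (cfg[[key]] <= 0 || cfg[[key]] >= 1)
      stop(key, " must be in (0, 1), got ", cfg[[key]])
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (!cfg$connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (length(cfg$k_range) != 2 || cfg$k_range[1] < 2 ||
      cfg$k_range[1] > cfg$k_range[2])
    stop("k_range must be c(min >= 2, max >= min)")
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  structure(cfg, class = "pipeline_config")
}

# deterministic per-stage seed fan-out from the single global seed:
# polynomial character hash of the stage name folded into [1, 2^31 - 2]
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483646 + 1)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full meta-analytic grouping pipeline
#'
#' Executes all four workflow steps plus the phenotype assessment and
#' writes every artifact into `out_dir`: MA matrix index, similarity
#' matrix, dendrogram (merge table and figure), stability report, selected
#' K with per-metric votes, MAG membership, per-MAG unthresholded and
#' thresholded ALE maps (NIfTI), cluster-label maps, peak tables, the
#' phenotype report, and a provenance manifest.  Rerunning with the same
#' config and seed reproduces every artifact bit-identically.
#'
#' @param config a [validate_config()] result, a config list, or a JSON
#'   config path.
#' @param corpus_override optionally, a ready-made `corpus` (or
#'   `synthetic_corpus`) to use instead of reading/simulating.
#' @return invisibly, a list with the run directory and the main in-memory
#'   results.
#' @export
run_pipeline <- function(config = list(), corpus_override = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "pipeline.log"), "wt")
  on.exit(close(logf))
  stage <- "setup"
  run <- function(name, expr) {
    stage <<- name
    log_line(logf, "stage ", name, " ...")
    force(expr)
  }
  tryCatch({
    t0 <- Sys.time()
    grid <- run("mask", load_mask(cfg$mask))
    corp <- run("corpus", {
      if (!is.null(corpus_override)) {
        if (inherits(corpus_override, "synthetic_corpus"))
          corpus_override$corpus
        else corpus_override
      } else if (!is.null(cfg$foci)) {
        read_corpus(cfg$foci, cfg$metadata, tal_method = cfg$tal_method)
      } else {
        generate_corpus(synthetic_spec(seed = stage_seed(cfg$seed,
                                                         "simulate")),
                        grid)$corpus
      }
    })
    spec <- kernel_spec(cfg$fwhm_subject_mm, cfg$fwhm_template_mm,
                        cfg$truncation_radius_sd, cfg$sample_size)
    if (cfg$k_range[2] > length(corp))
      stop("validation: K range upper bound ", cfg$k_range[2],
           " exceeds corpus size ", length(corp))

    mam <- run("ma_matrix", ma_matrix(corp, grid, spec))
    write.csv(data.frame(experiment_id = rownames(mam),
                         kernel_fwhm_mm = attr(mam, "kernel_fwhm_mm")),
              file.path(cfg$out_dir, "ma_index.csv"), row.names = FALSE)

    sim <- run("similarity", spearman_similarity(mam))
    write.csv(round(sim$rho, 6),
              file.path(cfg$out_dir, "similarity_matrix.csv"))

    tree <- run("clustering", hierarchical_cluster(sim))
    merge_tab <- data.frame(step = seq_len(nrow(tree$merge)),
                            left = tree$merge[, 1], right = tree$merge[, 2],
                            height = tree$height)
    write.csv(merge_tab, file.path(cfg$out_dir, "dendrogram_merges.csv"),
              row.names = FALSE)
    grDevices::png(file.path(cfg$out_dir, "dendrogram.png"),
                   width = 1200, height = 600)
    plot(tree, hang = -1, cex = 0.6, main = "CMHC dendrogram (1 - rho, average linkage)")
    grDevices::dev.off()

    stab <- run("stability",
                subsample_stability(mam,
                                    K_range = cfg$k_range[1]:cfg$k_range[2],
                                    fraction = cfg$subsample_fraction,
                                    n_iter = cfg$subsample_iterations,
                                    seed = stage_seed(cfg$seed, "stability")))
    write.csv(as.data.frame(stab),
              file.path(cfg$out_dir, "stability_report.csv"),
              row.names = FALSE)

    K <- run("select_k", select_k(stab, override = cfg$k_override))
    votes <- attr(K, "votes")
    writeLines(jsonlite::toJSON(list(K = unclass(K), votes = as.list(votes)),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(cfg$out_dir, "selected_k.json"))

    sol <- cut_tree(tree, K)
    mags <- run("prune", prune_small_groups(sol, cfg$min_group_size))
    write.csv(data.frame(experiment_id = names(sol$labels),
                         group = sol$labels,
                         retained = names(sol$labels) %in%
                           unlist(mags$retained)),
              file.path(cfg$out_dir, "mag_membership.csv"), row.names = FALSE)

    ale_results <- run("ale", {
      res <- list()
      for (g in names(mags$retained)) {
        exps <- corp$experiments[mags$retained[[g]]]
        r <- ale_analysis(exps, grid, spec,
                          alpha_voxel = cfg$alpha_voxel,
                          alpha_cluster = cfg$alpha_cluster,
                          n_permutations = cfg$n_permutations,
                          connectivity = cfg$connectivity,
                          voxel_null = cfg$voxel_null,
                          seed = stage_seed(cfg$seed, paste0("ale", g)))
        tag <- paste0("MAG", g)
        write_volume(r$ale$ale,
                     file.path(cfg$out_dir, paste0(tag, "_ale.nii.gz")))
        thr <- r$ale$ale$values
        sig_pos <- unlist(lapply(r$significant, `[[`, "mask_positions"))
        thr[!seq_along(thr) %in% sig_pos] <- 0
        write_volume(voxel_map(grid, thr),
                     file.path(cfg$out_dir,
                               paste0(tag, "_ale_thresholded.nii.gz")))
        labels_map <- numeric(grid$n_mask_voxels)
        for (cl in r$significant)
          labels_map[cl$mask_positions] <- cl$cluster_id
        write_volume(voxel_map(grid, labels_map),
                     file.path(cfg$out_dir, paste0(tag, "_clusters.nii.gz")))
        write.csv(r$peaks,
                  file.path(cfg$out_dir, paste0(tag, "_peaks.csv")),
                  row.names = FALSE)
        res[[g]] <- r
      }
      res
    })

    pheno <- run("phenotype", phenotype_report(corp, mags))
    write.csv(pheno, file.path(cfg$out_dir, "phenotype_report.csv"),
              row.names = FALSE)

    run("manifest", {
      manifest <- list(
        config = unclass(cfg),
        seed = cfg$seed,
        stage_seeds = sapply(c("simulate", "stability",
                               paste0("ale", names(mags$retained))),
                             function(s) stage_seed(cfg$seed, s)),
        n_experiments = length(corp),
        selected_k = unclass(K),
        retained_groups = lapply(mags$retained, length),
        r_version = as.character(getRversion()),
        package_version = as.character(packageVersion("magale")),
        elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA),
                 file.path(cfg$out_dir, "manifest.json"))
    })
    log_line(logf, "done")
    invisible(list(out_dir = cfg$out_dir, grid = grid, corpus = corp,
                   similarity = sim, tree = tree, stability = stab, K = K,
                   mags = mags, ale = ale_results, phenotype = pheno))
  }, error = function(e) {
    log_line(logf, "ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("pipeline halted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
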