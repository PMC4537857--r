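#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration of a full pipeline run.
#' All fields are plain values so the configuration is fully serializable;
#' [run_pipeline()] echoes it into the run directory as JSON.
#'
#' @param out_dir Output run directory.
#' @param seed Integer seed governing every stochastic stage.
#' @param threshold Binarization threshold for raw images (see
#'   [preprocess()]).
#' @param box_sizes Box-count scale ladder (pixels).
#' @param flare_factor,band_frac Stalk-band detection parameters.
#' @param r2_min,mad_k Outlier-filter parameters (see [filter_outliers()]).
#' @param manifest Optional CSV path (`sample_id`, `view_tag`, `path`)
#'   of raw images to phenotype; when `NULL` the phenotype stage runs on
#'   `n_demo_samples` synthetic root systems instead.
#' @param n_demo_samples Number of synthetic samples for the demo
#'   phenotype stage.
#' @param demo_canvas_px Canvas side for the demo samples.
#' @param phenotype_csv Optional plot-phenotype CSV for the diallel stage;
#'   when `NULL` a diallel phenotype table with known effects is simulated.
#' @param traits Trait columns analysed by the diallel stage.
#' @param n_clusters Clusters cut in the multivariate stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, threshold = 0.5,
                       box_sizes = 2L^(0:9), flare_factor = 1.5,
                       band_frac = 0.05, r2_min = 0.95, mad_k = 4,
                       manifest = NULL, n_demo_samples = 6L,
                       demo_canvas_px = 256L,
                       phenotype_csv = NULL,
                       traits = c("FD", "FA", "RA", "SD"),
                       n_clusters = 3L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              threshold = threshold, box_sizes = as.integer(box_sizes),
              flare_factor = flare_factor, band_frac = band_frac,
              r2_min = r2_min, mad_k = mad_k, manifest = manifest,
              n_demo_samples = as.integer(n_demo_samples),
              demo_canvas_px = as.integer(demo_canvas_px),
              phenotype_csv = phenotype_csv, traits = traits,
              n_clusters = as.integer(n_clusters))
  stopifnot(cfg$seed >= 0L, cfg$threshold >= 0, cfg$threshold <= 1,
            length(cfg$box_sizes) >= 3L, cfg$n_clusters >= 1L)
  class(cfg) <- "run_config"
  cfg
}

# FNV-1a style hash of the serialized configuration; the output
# directory is not part of the identity of a run
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  bytes <- as.integer(charToRaw(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                 null = "null")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_csv_prov <- function(df, path, cfg, stage) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# rootdiallel %s",
                       as.character(utils::packageVersion("rootdiallel"))),
               sprintf("# stage: %s", stage),
               sprintf("# config_hash: %s  seed: %d", config_hash(cfg),
                       cfg$seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV (skipping provenance header lines)
#'
#' @param path CSV path written by [run_pipeline()].
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

log_msg <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full phenotyping and genetics pipeline
#'
#' Executes the four stages in order, writing every product as CSV with a
#' provenance header (package version, stage, configuration hash, seed)
#' into the run directory:
#'
#' 1. **fixtures** — reference fractal rasters of known dimension plus a
#'    manifest, as a standing self-check of the fractal machinery.
#' 2. **phenotype** — either phenotypes the raw images listed in
#'    `config$manifest`, or renders `n_demo_samples` synthetic root
#'    systems and phenotypes their projections; per-view records are
#'    screened with [filter_outliers()].
#' 3. **diallel** — fits the generation-block diallel model per trait to
#'    `config$phenotype_csv` (or, by default, to a simulated diallel
#'    phenotype table with known effects), writing Type III tests,
#'    genetic effect estimates and entry-class contrasts.
#' 4. **multivariate** — per-class correlations, correlation-matrix PCA
#'    and Ward clustering of F1 entry means.
#'
#' Runs are idempotent for a fixed configuration and seed: re-running
#' produces byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  stage <- "fixtures"
  tryCatch({
    log_msg(logf, "[fixtures] writing reference fractal fixtures")
    write_fractal_fixtures(file.path(config$out_dir, "fixtures"),
                           seed = config$seed)

    stage <- "phenotype"
    pheno_views <- pipeline_phenotype_stage(config, logf)
    filt <- filter_outliers(pheno_views, r2_min = config$r2_min,
                            mad_k = config$mad_k)
    write_csv_prov(pheno_views,
                   file.path(config$out_dir, "phenotype_views.csv"),
                   config, "phenotype")
    writeLines(sprintf("%s view=%s: %s", filt$removed$plot_id,
                       filt$removed$view, filt$removed$reason),
               file.path(config$out_dir, "phenotype_removals.log"))

    stage <- "diallel"
    pheno <- if (!is.null(config$phenotype_csv)) {
      if (!file.exists(config$phenotype_csv)) {
        stop("phenotype CSV not found: ", config$phenotype_csv)
      }
      read_pipeline_csv(config$phenotype_csv)
    } else {
      log_msg(logf, "[diallel] simulating diallel phenotypes (seed ",
              config$seed, ")")
      simulate_root_traits(rng_seed = config$seed)
    }
    spec <- diallel_spec(
      parent_ids = sort(unique(stats::na.omit(
        c(pheno$parent1, pheno$parent2)))),
      check_ids = sort(unique(stats::na.omit(pheno$check_id))),
      env_ids = sort(unique(pheno$env)),
      reps_per_env = length(unique(pheno$rep)))
    ord <- normalize_cross_order(pheno, spec)
    pheno$parent1 <- ord$parent1
    pheno$parent2 <- ord$parent2
    design <- build_design(spec, pheno)
    for (tr in intersect(config$traits, names(pheno))) {
      fit <- fit_diallel(pheno, design, tr)
      write_csv_prov(type3_anova(fit),
                     file.path(config$out_dir,
                               sprintf("anova_%s.csv", tr)),
                     config, "diallel")
      ge <- genetic_effects(fit)
      write_csv_prov(ge$lines,
                     file.path(config$out_dir,
                               sprintf("effects_lines_%s.csv", tr)),
                     config, "diallel")
      write_csv_prov(ge$sca,
                     file.path(config$out_dir,
                               sprintf("effects_sca_%s.csv", tr)),
                     config, "diallel")
      write_csv_prov(estimate_contrasts(fit),
                     file.path(config$out_dir,
                               sprintf("contrasts_%s.csv", tr)),
                     config, "diallel")
      log_msg(logf, "[diallel] trait ", tr, " fitted (rank ", fit$rank,
              ", residual df ", fit$df_residual, ")")
    }

    stage <- "multivariate"
    traits <- intersect(config$traits, names(pheno))
    f1 <- pheno[pheno$entry_class == "F1", , drop = FALSE]
    means <- stats::aggregate(f1[traits],
                              by = list(entry_id = f1$entry_id),
                              FUN = mean, na.rm = TRUE)
    rownames(means) <- means$entry_id
    corr <- class_correlations(pheno, traits, entry_class = "F1")
    write_csv_prov(as.data.frame(corr$r),
                   file.path(config$out_dir, "correlations_F1.csv"),
                   config, "multivariate")
    Z <- zscore(means[traits])
    pca <- pca_correlation(means[traits])
    load_df <- data.frame(trait = rownames(pca$loadings),
                          round(pca$loadings[, 1:2, drop = FALSE], 4))
    write_csv_prov(load_df,
                   file.path(config$out_dir, "pca_loadings.csv"),
                   config, "multivariate")
    cl <- hcluster(Z, k = min(config$n_clusters, nrow(Z)))
    write_csv_prov(data.frame(entry_id = names(cl$labels),
                              cluster = unname(cl$labels)),
                   file.path(config$out_dir, "clusters.csv"),
                   config, "multivariate")
    log_msg(logf, "[multivariate] PCA eigenvalues: ",
            paste(sprintf("%.3f", pca$eigenvalues), collapse = ", "))
  }, error = function(e) {
    log_msg(logf, "[", stage, "] FAILED: ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(config$out_dir)
}

# put parent1/parent2 of F1 rows into spec order
normalize_cross_order <- function(pheno, spec) {
  is_f1 <- pheno$entry_class == "F1" & !is.na(pheno$parent1)
  i1 <- match(pheno$parent1, spec$parent_ids)
  i2 <- match(pheno$parent2, spec$parent_ids)
  swap <- is_f1 & !is.na(i1) & !is.na(i2) & i1 > i2
  p1 <- pheno$parent1; p2 <- pheno$parent2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  list(parent1 = p1, parent2 = p2)
}

pipeline_phenotype_stage <- function(config, logf) {
  if (!is.null(config$manifest)) {
    if (!file.exists(config$manifest)) {
      stop("manifest not found: ", config$manifest)
    }
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    missing <- man$path[!file.exists(man$path)]
    if (length(missing)) stop("image not found: ", missing[1L])
    samples <- split(man, man$sample_id)
    rows <- lapply(names(samples), function(sid) {
      sm <- samples[[sid]]
      get_img <- function(tag) {
        pth <- sm$path[sm$view_tag == tag]
        if (length(pth) != 1L) stop("sample ", sid,
                                    ": need exactly one view '", tag, "'")
        preprocess(png::readPNG(pth), threshold = config$threshold)
      }
      views <- list(side_views = stats::setNames(
        lapply(c("0", "90", "180", "270"), get_img),
        c("0", "90", "180", "270")),
        underside = get_img("underside"))
      phenotype_row(sid, views, config)
    })
    do.call(rbind, rows)
  } else {
    log_msg(logf, "[phenotype] rendering ", config$n_demo_samples,
            " synthetic samples (seed ", config$seed, ")")
    rows <- lapply(seq_len(config$n_demo_samples), function(i) {
      prm <- with_seed(config$seed + i, growth_params(
        cone_half_angle_deg = stats::runif(1, 20, 50),
        branch_prob = stats::runif(1, 0.3, 0.8),
        rng_seed = config$seed + i,
        canvas_size_px = config$demo_canvas_px,
        segment_length_px = config$demo_canvas_px * 0.3))
      views <- project_views(grow_root_system(prm))
      phenotype_row(sprintf("demo%03d", i), views, config)
    })
    do.call(rbind, rows)
  }
}

phenotype_row <- function(plot_id, views, config) {
  ph <- aggregate_sample(views, box_sizes = config$box_sizes,
                         flare_factor = config$flare_factor,
                         band_frac = config$band_frac)
  pv <- ph$per_view
  data.frame(plot_id = plot_id, view = pv$view, RA = pv$RA, SD = pv$SD,
             FD = ph$FD, FA = ph$FA, fit_r2 = ph$fit_r2,
             status = pv$status)
}
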