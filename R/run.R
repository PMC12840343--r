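#' End-to-end analysis runs
#'
#' `run_analysis()` sequences the full pipeline on a cohort: composition
#' summary, compartment volumetrics with rank-based group comparisons,
#' center-of-mass laterality statistics, per-group frequency maps with
#' summaries, group-vs-group differential maps, and ADIFFI permutation
#' cluster inference for every requested comparison x compartment cell. All
#' artifacts (CSV tables, NIfTI maps, JSON manifest) land in the output
#' directory; the manifest records the full configuration and seed, so a run
#' is reproducible from the manifest alone.
#'
#' @name run-analysis
NULL

.default_comparisons <- function() {
  data.frame(
    variable = c("mgmt", "subtype", "subtype", "subtype"),
    group_a = c("methylated", "MES", "MES", "RTK_I"),
    group_b = c("unmethylated", "RTK_I", "RTK_II", "RTK_II"),
    stringsAsFactors = FALSE)
}

#' Build a run configuration
#'
#' @param cohort path to a cohort CSV (see [load_cohort()]).
#' @param out_dir output directory.
#' @param comparisons data.frame with columns `variable`, `group_a`,
#'   `group_b`; defaults to the four standard comparisons (MGMT methylated
#'   vs unmethylated and the three subtype pairs, `OTHER` and missing MGMT
#'   excluded from pairwise testing but kept in summaries).
#' @param compartments compartments to analyze (default all three).
#' @param raw_p_threshold,n_permutations,connectivity,fwe_alpha ADIFFI
#'   settings, see [adiffi_config()].
#' @param seed master seed for the run.
#' @param midline_x_mm midsagittal plane for laterality, world mm.
#' @param label_map label dialect of the masks.
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort, out_dir,
                       comparisons = .default_comparisons(),
                       compartments = c("whole_tumor", "tumor_core",
                                        "non_enhancing"),
                       raw_p_threshold = 0.005, n_permutations = 500L,
                       connectivity = 26L, fwe_alpha = 0.05, seed = 1L,
                       midline_x_mm = 0, label_map = label_dialect(),
                       log_level = "info") {
  comparisons <- as.data.frame(comparisons, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "group_a", "group_b") %in% names(comparisons)),
            log_level %in% c("info", "debug", "quiet"))
  structure(list(cohort = cohort, out_dir = out_dir,
                 comparisons = comparisons, compartments = compartments,
                 raw_p_threshold = raw_p_threshold,
                 n_permutations = as.integer(n_permutations),
                 connectivity = as.integer(connectivity),
                 fwe_alpha = fwe_alpha, seed = as.integer(seed),
                 midline_x_mm = midline_x_mm, label_map = label_map,
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; `comparisons` is
#' a list of `{variable, group_a, group_b}` entries and `label_map` may be
#' given as the dialect string `"124"` or `"123"`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$comparisons)) {
    y$comparisons <- do.call(rbind, lapply(y$comparisons, as.data.frame))
  }
  if (!is.null(y$label_map) && is.character(y$label_map)) {
    y$label_map <- label_dialect(y$label_map)
  }
  do.call(run_config, y)
}

.logmsg <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]]) {
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  }
}

#' Run the full pipeline
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the run manifest (also written to `manifest.json`), invisibly:
#'   configuration, seed, artifact paths, and per-analysis ADIFFI summaries.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  loaded <- load_cohort(config$cohort, config$label_map)
  cohort <- loaded$cohort
  volumes <- loaded$volumes
  affine <- volumes[[1]]$affine
  .logmsg(config, "info", "loaded cohort: ", nrow(cohort), " patients")

  for (cmp in seq_len(nrow(config$comparisons))) {
    cc <- config$comparisons[cmp, ]
    for (g in c(cc$group_a, cc$group_b)) {
      if (!g %in% cohort[[cc$variable]]) {
        stop("requested group '", g, "' absent from cohort column '",
             cc$variable, "'")
      }
    }
  }

  artifacts <- list()
  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts[[name]] <<- p
    p
  }
  save_map <- function(data, name, datatype = "float32") {
    p <- file.path(config$out_dir, name)
    write_nifti(data, p, affine, datatype = datatype)
    artifacts[[name]] <<- p
    p
  }

  # --- cohort summary and volumetrics -------------------------------------
  save_csv(cohort_summary(cohort), "cohort_summary.csv")
  vols <- volume_table(volumes, cohort)
  save_csv(vols, "volumes.csv")

  vol_stats <- do.call(rbind, lapply(config$compartments, function(cp) {
    sub_rows <- function(variable, groups) {
      vg <- split(vols[[cp]], vols[[variable]])[groups]
      if (any(lengths(vg) < 2L)) return(NULL)
      ct <- compare_volumes(vg)
      data.frame(compartment = cp, variable = variable,
                 groups = paste(groups, collapse = "|"), test = ct$test,
                 statistic = ct$statistic, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }
    rbind(sub_rows("subtype", c("MES", "RTK_I", "RTK_II")),
          sub_rows("mgmt", c("methylated", "unmethylated")))
  }))
  save_csv(vol_stats, "volume_stats.csv")
  .logmsg(config, "info", "volumetrics done")

  # --- laterality ----------------------------------------------------------
  lat_rows <- list()
  locations <- list()
  for (cp in intersect(c("whole_tumor", "tumor_core"), config$compartments)) {
    loc <- locate_cohort(volumes, cohort, cp, config$midline_x_mm)
    locations[[cp]] <- loc
    save_csv(loc, paste0("locations_", cp, ".csv"))
    keep <- !is.na(loc$hemisphere) & loc$hemisphere != "midline"
    gof <- laterality_gof(sum(loc$hemisphere[keep] == "right"),
                          sum(loc$hemisphere[keep] == "left"))
    lat_rows[[length(lat_rows) + 1L]] <- data.frame(
      compartment = cp, test = "gof_overall", groups = "all",
      statistic = gof$statistic, p_value = gof$p_value)
    for (variable in unique(config$comparisons$variable)) {
      grp <- if (variable == "subtype") c("MES", "RTK_I", "RTK_II")
             else setdiff(unique(loc[[variable]]), "missing")
      tab <- hemisphere_counts(loc, variable, grp)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      ct <- laterality_contingency(tab)
      lat_rows[[length(lat_rows) + 1L]] <- data.frame(
        compartment = cp, test = paste0("contingency_", variable),
        groups = paste(grp, collapse = "|"),
        statistic = ct$statistic, p_value = ct$p_value)
    }
  }
  save_csv(do.call(rbind, lat_rows), "laterality.csv")
  .logmsg(config, "info", "laterality done")

  # --- maps and ADIFFI ------------------------------------------------------
  analyses <- list()
  cell <- 0L
  map_summaries <- list()
  for (cmp in seq_len(nrow(config$comparisons))) {
    cc <- config$comparisons[cmp, ]
    idx_a <- which(cohort[[cc$variable]] == cc$group_a)
    idx_b <- which(cohort[[cc$variable]] == cc$group_b)
    for (cp in config$compartments) {
      cell <- cell + 1L
      tag <- paste(cc$group_a, "vs", cc$group_b, cp, sep = "_")
      masks_a <- lapply(volumes[idx_a], derive_compartment, compartment = cp)
      masks_b <- lapply(volumes[idx_b], derive_compartment, compartment = cp)
      fa <- frequency_map(masks_a, cc$group_a, cp, affine)
      fb <- frequency_map(masks_b, cc$group_b, cp, affine)
      save_map(fa$values, paste0("freq_", cc$group_a, "_", cp, ".nii"))
      save_map(fb$values, paste0("freq_", cc$group_b, "_", cp, ".nii"))
      dm <- differential_map(fa, fb)
      save_map(dm$values, paste0("diff_", tag, ".nii"))
      for (f in list(fa, fb)) {
        s <- map_summary(f)
        map_summaries[[length(map_summaries) + 1L]] <- data.frame(
          group = f$group_label, compartment = cp,
          max_frequency = s$max_frequency,
          n_above_10 = s$n_above[["gt_10"]],
          n_above_20 = s$n_above[["gt_20"]])
      }
      acfg <- adiffi_config(config$raw_p_threshold, config$n_permutations,
                            config$connectivity, config$fwe_alpha,
                            seed = derive_seed(config$seed, 5L, cell))
      res <- adiffi(masks_a, masks_b, acfg,
                    group_labels = c(cc$group_a, cc$group_b), affine = affine)
      save_map(res$p_map, paste0("pmap_", tag, ".nii"))
      sig_map <- array(0L, dim = dim(res$p_map))
      for (k in seq_along(res$clusters)) {
        if (res$clusters[[k]]$significant) {
          sig_map[res$clusters[[k]]$voxels] <- k
        }
      }
      save_map(sig_map, paste0("sigclusters_", tag, ".nii"),
               datatype = "int16")
      save_csv(cluster_table(res), paste0("clusters_", tag, ".csv"))
      analyses[[tag]] <- list(
        variable = cc$variable, group_a = cc$group_a, group_b = cc$group_b,
        compartment = cp, n_a = length(idx_a), n_b = length(idx_b),
        cluster_size_threshold = res$cluster_size_threshold,
        n_significant_clusters = res$n_significant_clusters,
        min_raw_p = res$min_raw_p,
        n_significant_voxels = res$n_significant_voxels,
        corrected_p = res$corrected_p)
      .logmsg(config, "info", "ADIFFI ", tag, ": ",
              res$n_significant_clusters, " significant cluster(s), ",
              res$n_significant_voxels, " voxels")
    }
  }
  save_csv(do.call(rbind, map_summaries), "map_summaries.csv")

  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config)[setdiff(names(config), "label_map")],
                       cfg_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "adiffi",
    version = as.character(utils::packageVersion("adiffi")),
    seed = config$seed,
    config_path = cfg_json,
    config_md5 = unname(tools::md5sum(cfg_json)),
    label_map = as.list(config$label_map),
    n_patients = nrow(cohort),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = artifacts,
    analyses = analyses)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logmsg(config, "info", "run complete: ", length(artifacts), " artifacts")
  invisible(manifest)
}
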