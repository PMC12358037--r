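# Orchestration of the full study workflow: process -> vision -> markers ->
# metrics -> statistics -> PCA, with provenance-stamped tabular outputs.

#' Analysis configuration
#'
#' All knobs of the full workflow in one list. With no file paths supplied
#' the synthetic study set and a synthetic pure-birth tree are generated
#' from `seed`.
#'
#' @param spectra_file,tree_file optional input paths (wide spectra dialect;
#'   Newick with branch lengths). `NULL` means synthetic.
#' @param groups optional named vector label -> colour class (required when
#'   `spectra_file` is supplied).
#' @param counts synthetic class counts, see [make_study_set()].
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it and it is recorded in every output header.
#' @param models vision models to run.
#' @param span smoothing span for spectrum processing.
#' @param thresholds named chromatic thresholds (EU) per model.
#' @param markers a [marker_settings()].
#' @param marker_classes classes whose spectra enter marker-point analysis.
#' @param optima discrimination optima (nm) for MAD/minAD.
#' @param n_sim phylANOVA simulation count.
#' @param out_dir output directory for [write_report()]; `NULL` writes
#'   nothing.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(spectra_file = NULL, tree_file = NULL,
                            groups = NULL,
                            counts = c(green = 19, green_yellow = 11,
                                       blue_violet = 28, pink = 25,
                                       white = 9, yellow = 38),
                            seed = 1,
                            models = c("hexagon", "fly"),
                            span = 0.20,
                            thresholds = default_thresholds,
                            markers = marker_settings(),
                            marker_classes = c("green", "green_yellow",
                                               "blue_violet"),
                            optima = c(400, 500),
                            n_sim = 10000,
                            out_dir = NULL) {
  structure(list(spectra_file = spectra_file, tree_file = tree_file,
                 groups = groups, counts = counts, seed = seed,
                 models = match.arg(models, several.ok = TRUE),
                 span = span, thresholds = thresholds, markers = markers,
                 marker_classes = marker_classes, optima = optima,
                 n_sim = n_sim, out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()].
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files needs the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$markers)) cfg$markers <- do.call(marker_settings, cfg$markers)
  if (!is.null(cfg$counts)) cfg$counts <- unlist(cfg$counts)
  if (!is.null(cfg$thresholds)) cfg$thresholds <- unlist(cfg$thresholds)
  do.call(analysis_config, cfg)
}

# deterministic FNV-1a hash of the config for output provenance headers
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the full analysis workflow
#'
#' Executes every stage of the study pipeline: acquire spectra (file or
#' synthetic), process them (local-regression smoothing, negative-value
#' correction), map them into both vision models, tally hue sectors and
#' below-threshold counts per colour class, detect marker points and compute
#' the binned frequencies and MAD/minAD metrics, run the phylogenetic ANOVAs
#' (chromatic and achromatic contrasts: green vs green-yellow and across all
#' classes; MAD/minAD across marker classes), and compute the PCA grouping
#' check. Deterministic given `cfg$seed`.
#'
#' @param cfg an [analysis_config()].
#' @return a `study_report` list of tables: `spectra`, `contrasts`,
#'   `sector_tally`, `threshold_tally`, `marker_points`, `marker_bins`,
#'   `marker_metrics`, `excluded_labels`, `phylanova`, `posthoc`, `pca`,
#'   plus `seed` and `config_hash`. Written to `cfg$out_dir` if set.
#' @export
run_full_analysis <- function(cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))

  # -- stage: data -----------------------------------------------------------
  if (is.null(cfg$spectra_file)) {
    ss <- make_study_set(cfg$counts, seed = cfg$seed)
  } else {
    ss <- read_spectra(cfg$spectra_file)
    if (is.null(cfg$groups)) stop("[data] groups required with spectra_file", call. = FALSE)
    ss$groups <- cfg$groups[labels(ss)]
  }
  stage_log("data", 0L, length(ss))

  # -- stage: process --------------------------------------------------------
  proc <- fix_negative(smooth_spectra(ss, span = cfg$span))
  validate_spectra(proc)
  stage_log("process", length(ss), length(proc))

  # -- stage: vision ---------------------------------------------------------
  loci <- do.call(rbind, lapply(cfg$models, function(m) {
    key <- if (m == "fly") "fly" else "hexagon"
    ctx <- viewing_context(key, threshold = unname(cfg$thresholds[key]))
    colour_loci(proc, ctx)
  }))
  sector_tally <- as.data.frame(table(model = loci$model, group = loci$group,
                                      sector = loci$sector),
                                responseName = "n")
  sector_tally <- sector_tally[sector_tally$n > 0, ]
  below <- stats::aggregate(list(n_below = !loci$above_threshold),
                            by = list(model = loci$model, group = loci$group),
                            FUN = sum)
  below$n_total <- stats::aggregate(list(n = loci$above_threshold),
                                    by = list(model = loci$model,
                                              group = loci$group),
                                    FUN = length)$n
  stage_log("vision", length(proc), nrow(loci))

  # -- stage: markers --------------------------------------------------------
  keep <- labels(proc)[proc$groups %in% cfg$marker_classes]
  mss <- proc[keep]
  mps <- detect_marker_points(mss, cfg$markers)
  bins <- bin_marker_points(mps, binwidth = 10, groups = mss$groups)
  metrics <- marker_metrics(mps, optima = cfg$optima)
  metrics$group <- unname(mss$groups[metrics$label])
  excluded <- attr(metrics, "excluded")
  mp_table <- data.frame(
    label = names(mps),
    group = unname(mss$groups[names(mps)]),
    marker_points = vapply(mps, function(m)
      paste(round(m$points_nm, 1), collapse = ";"), character(1)),
    row.names = NULL)
  stage_log("markers", length(mss), nrow(mp_table))

  # -- stage: phylostats -----------------------------------------------------
  tree <- if (is.null(cfg$tree_file)) {
    make_yule_tree(length(proc), seed = cfg$seed + 1000L, labels = labels(proc))
  } else {
    ape::read.tree(cfg$tree_file)
  }
  comparisons <- list()
  gg <- c("green", "green_yellow")
  for (m in cfg$models) {
    sub <- loci[loci$model == m, ]
    comparisons[[paste0("chromatic_", m, "_green_vs_gy")]] <-
      list(values = sub$chromatic_EU[sub$group %in% gg],
           labels = sub$label[sub$group %in% gg],
           groups = sub$group[sub$group %in% gg])
    comparisons[[paste0("chromatic_", m, "_all_classes")]] <-
      list(values = sub$chromatic_EU, labels = sub$label, groups = sub$group)
  }
  if ("hexagon" %in% cfg$models) {
    sub <- loci[loci$model == "hexagon", ]
    comparisons[["achromatic_hexagon_green_vs_gy"]] <-
      list(values = sub$achromatic_EU[sub$group %in% gg],
           labels = sub$label[sub$group %in% gg],
           groups = sub$group[sub$group %in% gg])
    comparisons[["achromatic_hexagon_all_classes"]] <-
      list(values = sub$achromatic_EU, labels = sub$label, groups = sub$group)
  }
  ok <- !is.na(metrics$MAD)
  for (metric in c("MAD", paste0("minAD_", cfg$optima))) {
    comparisons[[paste0(metric, "_marker_classes")]] <-
      list(values = metrics[[metric]][ok], labels = metrics$label[ok],
           groups = metrics$group[ok])
  }
  res_rows <- list(); ph_rows <- list()
  i <- 0L
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    i <- i + 1L
    sub_tree <- ape::keep.tip(tree, cmp$labels)
    traits <- data.frame(label = cmp$labels, value = cmp$values,
                         group = cmp$groups)
    fit <- phyl_anova(sub_tree, traits, n_sim = cfg$n_sim,
                      seed = cfg$seed + 2000L + i)
    res_rows[[nm]] <- data.frame(comparison = nm, F = fit$f_observed,
                                 df1 = fit$df1, df2 = fit$df2,
                                 p_phylo = fit$p_phylo, n_sim = fit$n_sim,
                                 seed = fit$seed)
    ph <- fit$posthoc; ph$comparison <- nm
    ph_rows[[nm]] <- ph
  }
  phyl_table <- do.call(rbind, c(res_rows, make.row.names = FALSE))
  posthoc_table <- do.call(rbind, c(ph_rows, make.row.names = FALSE))
  stage_log("phylostats", nrow(loci), nrow(phyl_table))

  # -- stage: pca ------------------------------------------------------------
  pca <- validate_grouping_pca(proc)
  stage_log("pca", length(proc), nrow(pca))

  report <- structure(
    list(spectra = as.data.frame(proc), contrasts = loci,
         sector_tally = sector_tally, threshold_tally = below,
         marker_points = mp_table, marker_bins = bins,
         marker_metrics = metrics, excluded_labels = excluded,
         phylanova = phyl_table, posthoc = posthoc_table, pca = pca,
         seed = cfg$seed, config_hash = config_hash(cfg)),
    class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed=%d, config=%s\n", x$seed, x$config_hash))
  cat(sprintf("  %d spectra, %d contrast rows, %d phylANOVA comparisons\n",
              ncol(x$spectra) - 1L, nrow(x$contrasts), nrow(x$phylanova)))
  invisible(x)
}

#' Write a study report to delimited text files
#'
#' One tab-separated file per table, each with a commented provenance header
#' (package version, master seed, config hash). Deterministic: the same
#' report writes byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# florivis %s; seed=%d; config=%s",
                 as.character(utils::packageVersion("florivis")),
                 report$seed, report$config_hash)
  tabs <- c("spectra", "contrasts", "sector_tally", "threshold_tally",
            "marker_points", "marker_bins", "marker_metrics", "phylanova",
            "posthoc", "pca")
  for (nm in tabs) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, open = "wb")  # binary: stable newlines across platforms
    writeLines(hdr, con)
    utils::write.table(format(report[[nm]], digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  writeLines(c(hdr, report$excluded_labels %||% character(0)),
             file.path(dir, "excluded_labels.txt"))
  invisible(dir)
}

#' PCA grouping check
#'
#' Principal component analysis of the raw reflectance matrix (wavelengths
#' as features, centred, unscaled), used to check that declared colour
#' classes form coherent clusters. Reports the scores of the first two
#' components and their explained-variance fractions.
#'
#' @param ss a `spec_set` with at least 3 spectra.
#' @return data.frame `label, group, PC1, PC2` with attributes `explained`
#'   (length-2 numeric) and `rotation`.
#' @export
validate_grouping_pca <- function(ss) {
  stopifnot(inherits(ss, "spec_set"))
  if (length(ss) < 3) stop("PCA needs at least 3 spectra", call. = FALSE)
  X <- t(ss$refl)
  tot <- sum(apply(X, 2, stats::var))
  if (tot < 1e-12) {
    warning("all spectra identical; explained variance undefined", call. = FALSE)
    out <- data.frame(label = labels(ss),
                      group = if (!is.null(ss$groups)) unname(ss$groups) else NA,
                      PC1 = 0, PC2 = 0)
    attr(out, "explained") <- c(NA_real_, NA_real_)
    return(out)
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  out <- data.frame(label = labels(ss),
                    group = if (!is.null(ss$groups)) unname(ss$groups) else NA,
                    PC1 = p$x[, 1], PC2 = p$x[, 2], row.names = NULL)
  attr(out, "explained") <- (p$sdev^2 / sum(p$sdev^2))[1:2]
  attr(out, "rotation") <- p$rotation[, 1:2]
  out
}
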