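#' Run configuration for the end-to-end pipelines
#'
#' Bundles a manifest path, an output directory, the quantification
#' configuration and the analysis options for [run_dab_pipeline()] and
#' [run_coloc_pipeline()]. The configuration serializes losslessly to JSON in
#' the run manifest, together with its MD5 hash and the seed, so any run can
#' be reproduced exactly.
#'
#' @param manifest path to the input manifest CSV (see the pipeline docs for
#'   the expected columns).
#' @param output_dir directory for all outputs (created if missing).
#' @param quant a [quant_config()].
#' @param probit_mode probit mode for the ROC stage, see [probit_transform()].
#' @param mask_mode colocalization mask mode, see [coloc_mask()].
#' @param seed integer seed recorded in the run manifest and used for any
#'   stochastic step.
#' @param verbose emit per-core progress messages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(manifest, output_dir, quant = quant_config(),
                       probit_mode = "proportion",
                       mask_mode = "either_above", seed = 1L,
                       verbose = FALSE) {
  stopifnot(inherits(quant, "quant_config"))
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  structure(list(manifest = manifest, output_dir = output_dir, quant = quant,
                 probit_mode = probit_mode, mask_mode = mask_mode,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

config_json <- function(config) {
  ser <- config
  ser$quant <- unclass(ser$quant)
  jsonlite::toJSON(unclass(ser), auto_unbox = TRUE, digits = NA, null = "null")
}

write_run_manifest <- function(config, path, extra = list()) {
  js <- config_json(config)
  tmp <- tempfile(); writeLines(as.character(js), tmp)
  info <- c(list(config = jsonlite::fromJSON(js),
                 config_md5 = unname(tools::md5sum(tmp)),
                 seed = config$seed),
            extra)
  unlink(tmp)
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

write_csv_out <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the DAB quantification and cohort analysis pipeline
#'
#' Orchestrates the full brightfield analysis. The manifest CSV must have
#' columns `core_id`, `image_path`, `marker_name`, `diagnosis`
#' (`benign`/`malignant`) and may carry `gleason` and `relapse`. Every image
#' is quantified blind — the quantification step receives only the image and
#' the configuration, never the label columns — and labels are joined to the
#' results afterwards. Unreadable or corrupt images are skipped with a logged
#' reason and counted, mirroring the "usable cores" accounting of
#' tissue-microarray spreadsheets.
#'
#' Outputs written to `config$output_dir`:
#' \describe{
#'   \item{quant_results.csv}{per-core [quantify_core()] rows joined to labels
#'     (columns: core_id, count, total_area, average_size, area_fraction,
#'     tissue_area, normalized_signal, marker_name, diagnosis, gleason,
#'     relapse).}
#'   \item{group_stats.csv}{per-marker group means, SEs, folds and the
#'     Mann-Whitney comparison ([cohort_group_stats()]).}
#'   \item{roc_points.csv / roc_summary.csv}{per-marker operating points
#'     (criterion, sensitivity, 1-specificity, LR+, LR-) on the
#'     probit-transformed area fractions, plus empirical and binormal AUCs.}
#'   \item{logistic_pairs.csv}{for every marker pair, the two-marker logistic
#'     fit and its in-sample percent correctly identified (written only when
#'     at least two markers are present).}
#'   \item{run_manifest.json}{the serialized configuration, its MD5 hash, the
#'     seed, usable-core counts and skip reasons.}
#' }
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `quant` (the per-core table),
#'   `group_stats`, `roc_summary`, `logistic`, `skipped`, and the output
#'   paths.
#' @export
run_dab_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("core_id", "image_path", "marker_name", "diagnosis")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  skipped <- list()
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    res <- tryCatch(
      quantify_core(read_core_image(man$image_path[i], man$core_id[i]),
                    config$quant),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        list(core_id = man$core_id[i], reason = conditionMessage(res))
      if (config$verbose)
        message("skipping core ", man$core_id[i], ": ", conditionMessage(res))
      next
    }
    rows[[i]] <- res
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("no usable cores", call. = FALSE)
  quant <- do.call(rbind, rows[ok])

  # labels are joined only after quantification (blind-by-design); the join
  # is by manifest row, so the same core may recur across markers
  label_cols <- intersect(c("marker_name", "diagnosis", "gleason", "relapse"),
                          names(man))
  quant <- cbind(quant, man[ok, label_cols, drop = FALSE])
  quant <- quant[order(quant$marker_name, quant$core_id), ]
  rownames(quant) <- NULL
  class(quant) <- "data.frame"
  write_csv_out(quant, file.path(config$output_dir, "quant_results.csv"))

  stats <- cohort_group_stats(quant, value = "area_fraction")
  write_csv_out(stats, file.path(config$output_dir, "group_stats.csv"))

  roc_points <- list(); roc_summary <- list()
  for (mk in unique(quant$marker_name)) {
    d <- quant[quant$marker_name == mk, ]
    if (length(unique(d$diagnosis)) < 2L) next
    sc <- probit_transform(pmin(d$area_fraction, 100), config$probit_mode)
    lb <- as.integer(d$diagnosis == "malignant")
    roc <- empirical_roc(sc, lb)
    bn <- binormal_roc(sc, lb)
    pts <- roc$operating_points
    pts$marker <- mk
    roc_points[[mk]] <- pts[, c("marker", setdiff(names(pts), "marker"))]
    roc_summary[[mk]] <- data.frame(marker = mk,
                                    auc_empirical = roc$auc_empirical,
                                    auc_binormal = bn$auc_binormal,
                                    binormal_a = bn$a, binormal_b = bn$b,
                                    stringsAsFactors = FALSE)
  }
  roc_points <- do.call(rbind, roc_points)
  roc_summary <- do.call(rbind, roc_summary)
  if (!is.null(roc_points)) {
    write_csv_out(roc_points, file.path(config$output_dir, "roc_points.csv"))
    write_csv_out(roc_summary, file.path(config$output_dir, "roc_summary.csv"))
  }

  logistic <- NULL
  markers <- sort(unique(quant$marker_name))
  if (length(markers) >= 2L) {
    combos <- combn(markers, 2L)
    lst <- lapply(seq_len(ncol(combos)), function(j) {
      m1 <- combos[1, j]; m2 <- combos[2, j]
      d1 <- quant[quant$marker_name == m1,
                  c("core_id", "area_fraction", "diagnosis")]
      d2 <- quant[quant$marker_name == m2, c("core_id", "area_fraction")]
      dd <- merge(d1, d2, by = "core_id", suffixes = c("_1", "_2"))
      if (nrow(dd) < 4L || length(unique(dd$diagnosis)) < 2L) return(NULL)
      fit <- fit_logistic_pair(dd$area_fraction_1, dd$area_fraction_2,
                               as.integer(dd$diagnosis == "malignant"))
      data.frame(marker_pair = paste(m1, m2, sep = "+"),
                 beta0 = fit$beta0, beta1 = fit$beta1, beta2 = fit$beta2,
                 pct_correct = fit$pct_correct,
                 separation_flag = fit$separation,
                 converged = fit$converged, n_used = fit$n_used,
                 stringsAsFactors = FALSE)
    })
    logistic <- do.call(rbind, lst)
    if (!is.null(logistic))
      write_csv_out(logistic, file.path(config$output_dir,
                                        "logistic_pairs.csv"))
  }

  write_run_manifest(config,
                     file.path(config$output_dir, "run_manifest.json"),
                     extra = list(n_manifest = nrow(man),
                                  n_usable = nrow(quant),
                                  skipped = skipped))
  invisible(list(quant = quant, group_stats = stats,
                 roc_summary = roc_summary, logistic = logistic,
                 skipped = skipped, output_dir = config$output_dir))
}

#' Run the colocalization stratification pipeline
#'
#' Orchestrates the fluorescence analysis. The manifest CSV must have columns
#' `core_id`, `pair_id`, `relapse` (`yes`/`no`), `path_a`, `path_b` (one
#' multi-page 16-bit TIFF per channel) and may name the channels with
#' `channel_a`, `channel_b`. Each stack is max-projected, masked
#' (`config$mask_mode`) and reduced to a Pearson coefficient; cores are then
#' matched into non-relapse/relapse pairs by `pair_id` and compared with a
#' paired t-test. A `pair_id` lacking exactly one core per arm raises an
#' error listing the offending ids.
#'
#' Outputs written to `config$output_dir`: `coloc_results.csv` (core_id,
#' pair_id, relapse, channel_pair, r, n_pixels, mask_mode),
#' `coloc_summary.csv` (one row per group: n, mean r, SD; plus the paired p),
#' and `run_manifest.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `results` (per-core coefficients),
#'   `comparison` (see [compare_coloc_groups()]) and the output paths.
#' @export
run_coloc_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("core_id", "pair_id", "relapse", "path_a", "path_b")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  res <- lapply(seq_len(nrow(man)), function(i) {
    cha <- read_fluor_channel(man$path_a[i])
    chb <- read_fluor_channel(man$path_b[i])
    st <- fluor_stack(list(a = cha, b = chb), core_id = man$core_id[i])
    pr <- max_project(st)
    a <- channel_matrix(pr$channels$a); b <- channel_matrix(pr$channels$b)
    msk <- coloc_mask(a, b, mode = config$mask_mode)
    pair_lab <- if (all(c("channel_a", "channel_b") %in% names(man)))
      paste(man$channel_a[i], man$channel_b[i], sep = "~") else "a~b"
    cc <- pearson_coloc(a, b, msk, channel_pair = pair_lab)
    data.frame(core_id = man$core_id[i], pair_id = man$pair_id[i],
               relapse = man$relapse[i], channel_pair = cc$channel_pair,
               r = cc$pearson_r, n_pixels = cc$n_pixels_used,
               mask_mode = cc$mask_mode, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  tab <- table(res$pair_id, res$relapse)
  bad <- if (!identical(sort(colnames(tab)), c("no", "yes"))) {
    rownames(tab)
  } else {
    rownames(tab)[!(tab[, "no"] == 1 & tab[, "yes"] == 1)]
  }
  if (length(bad) > 0)
    stop("unmatched pair ids (need one relapse='yes' and one 'no' per pair): ",
         paste(bad, collapse = ", "), call. = FALSE)
  res <- res[order(res$pair_id, res$relapse), ]
  nr <- res$r[res$relapse == "no"]
  rl <- res$r[res$relapse == "yes"]
  cmp <- compare_coloc_groups(nr, rl)

  write_csv_out(res, file.path(config$output_dir, "coloc_results.csv"))
  summ <- data.frame(group = c("nonrelapse", "relapse"),
                     n = c(cmp$n_pairs, cmp$n_pairs),
                     mean_r = c(cmp$mean_nonrelapse, cmp$mean_relapse),
                     sd_r = c(cmp$sd_nonrelapse, cmp$sd_relapse),
                     p_two_sided = cmp$p_two_sided,
                     stringsAsFactors = FALSE)
  write_csv_out(summ, file.path(config$output_dir, "coloc_summary.csv"))
  write_run_manifest(config,
                     file.path(config$output_dir, "run_manifest.json"),
                     extra = list(n_cores = nrow(res)))
  invisible(list(results = res, comparison = cmp,
                 output_dir = config$output_dir))
}
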