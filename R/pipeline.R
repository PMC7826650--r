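#' Extract a two-visit feature table from segmented lesions
#'
#' Runs [extract_features()] over a list of lesion ROIs and assembles the
#' long-form table consumed by the statistical stages, recording the median
#' number of grey-level bins across lesions and visits (the standard summary
#' of discretisation granularity).
#'
#' @param rois list of entries, each a list with `lesion_id`, `visit`,
#'   `image` (3D array), `mask` (3D 0/1 array), and `voxel_size`.
#' @param normalise apply intensity normalisation before extraction.
#' @param bin_width discretisation bin width.
#' @return List with `table` (a [feature_table()]) and `median_n_bins`.
#' @export
extract_dataset <- function(rois, normalise = FALSE, bin_width = 5) {
  stopifnot(is.list(rois), length(rois) >= 1L)
  rows <- vector("list", length(rois))
  bins <- numeric(length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    fv <- extract_features(r$image, r$mask, voxel_size = r$voxel_size,
                           bin_width = bin_width, normalise = normalise)
    bins[i] <- attr(fv, "n_bins")
    rows[[i]] <- data.frame(lesion_id = as.character(r$lesion_id),
                            visit = as.integer(r$visit),
                            feature = names(fv), value = as.numeric(fv),
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  long <- long[!is.na(long$value), , drop = FALSE]
  list(table = feature_table(long), median_n_bins = median(bins))
}

# resolve one configured dataset entry into a paired feature table
.resolve_dataset <- function(entry, bin_width) {
  median_bins <- NA_real_
  if (!is.null(entry$table)) {
    ft <- if (inherits(entry$table, "feature_table")) entry$table
          else read_feature_tables(entry$table)
  } else if (!is.null(entry$paths)) {
    ft <- read_feature_tables(entry$paths)
  } else if (!is.null(entry$rois)) {
    ex <- extract_dataset(entry$rois, normalise = isTRUE(entry$normalised),
                          bin_width = bin_width)
    ft <- ex$table
    median_bins <- ex$median_n_bins
  } else if (!is.null(entry$synthetic)) {
    syn <- entry$synthetic
    specs <- lapply(seq_along(syn$features), function(i) {
      f <- syn$features[[i]]
      random_effects_spec(mu = f$mu, sigma_b = f$sigma_b,
                          sigma_w = f$sigma_w,
                          n_lesions = syn$n_lesions,
                          n_visits = if (is.null(syn$n_visits)) 2L else
                            syn$n_visits,
                          lambda_skew = f$lambda_skew,
                          feature = if (is.null(f$name))
                            sprintf("feature_%02d", i) else f$name)
    })
    # each synthetic dataset consumes its own block of the RNG stream
    ft <- simulate_feature_table(specs,
                                 seed = sample.int(.Machine$integer.max, 1L))
  } else {
    stop("dataset entry needs one of: table, paths, rois, synthetic")
  }
  ft <- ft_pair_visits(ft)
  if (length(unique(ft$lesion_id)) < 2L) stop("dataset has fewer than 2 paired lesions")
  list(table = ft, median_n_bins = median_bins)
}

# ICC + RC rows for every feature of a (possibly transformed) table
.dataset_icc_rc <- function(ft, records, dataset_id, sequence, normalised,
                            variant, conf_level = 0.95) {
  feats <- ft_features(ft)
  rows <- lapply(feats, function(f) {
    m <- ft_matrix(ft, f)
    rec <- records[records$feature == f, , drop = FALSE]
    if (nrow(m) < 2L || sd(as.vector(m)) == 0) {
      return(NULL)  # degenerate feature, excluded with reason logged upstream
    }
    ic <- icc_1_1(m, conf_level = conf_level)
    rcres <- rc(m, conf_level = conf_level)
    data.frame(dataset = dataset_id, sequence = sequence,
               normalised = normalised, variant = variant, feature = f,
               status = if (nrow(rec)) rec$status else NA_character_,
               lambda = if (nrow(rec)) rec$lambda else NA_real_,
               icc = ic$icc, icc_low = ic$ci_low, icc_high = ic$ci_high,
               rc = rcres$rc, rc_low = rcres$ci_low, rc_high = rcres$ci_high,
               wsd = rcres$wsd, n = ic$n, k = ic$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
}

#' Run the full repeatability study workflow
#'
#' Orchestrates the statistical workflow over a set of datasets (one per MR
#' sequence and normalisation setting): visit pairing, Gaussianity gating and
#' Box-Cox transformation, ICC(1,1) and RC estimation with confidence
#' intervals for both the original and Box-Cox variants of every dataset,
#' Fisher-Z comparisons (Box-Cox effect within dataset, sequence pairs,
#' normalisation effect within sequence), and the cross-dataset CoV of ICCs.
#' With 4 sequences, each with and without normalisation, the report covers
#' the full 16 dataset combinations (4 sequences x 2 normalisations x 2
#' transformation variants).
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `datasets`: list of entries, each with `sequence` (label),
#'     `normalised` (logical), and one of `table` (a [feature_table()] or
#'     file path(s)), `paths`, `rois` (see [extract_dataset()]), or
#'     `synthetic` (list with `n_lesions`, optional `n_visits`, and
#'     `features`: a list of `mu`/`sigma_b`/`sigma_w`/`lambda_skew`/`name`
#'     lists);
#'   * `alpha` (default 0.05), `n_features_bonferroni` (default: number of
#'     features per dataset), `bin_width` (default 5), `boxcox_method`
#'     (default `"ppcc"`), `seed` (default 1).
#' @param quiet suppress per-stage progress messages.
#' @return A `study_report`: list with `icc_rc` (per-feature estimates for
#'   every dataset combination), `transformation_counts`, `comparisons`,
#'   `comparison_summary`, `cov`, `median_bins`, and `provenance`.
#' @export
run_study <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$datasets) >= 1L)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  stopifnot(alpha > 0, alpha < 1)
  bin_width <- if (is.null(config$bin_width)) 5 else config$bin_width
  stopifnot(bin_width > 0)
  method <- if (is.null(config$boxcox_method)) "ppcc" else config$boxcox_method
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  datasets <- config$datasets
  ids <- vapply(datasets, function(d) {
    paste0(d$sequence, "_", if (isTRUE(d$normalised)) "norm" else "raw")
  }, character(1L))
  if (anyDuplicated(ids)) stop("duplicate (sequence, normalised) dataset entries")

  resolved <- list()
  classified <- list()
  icc_rc <- list()
  median_bins <- data.frame(dataset = ids, median_n_bins = NA_real_,
                            stringsAsFactors = FALSE)
  n_feats_bonf <- config$n_features_bonferroni

  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    res <- .resolve_dataset(d, bin_width)
    ft <- res$table
    median_bins$median_n_bins[i] <- res$median_n_bins
    nf <- length(ft_features(ft))
    say("dataset %s: %d paired lesions, %d features", ids[i],
        length(unique(ft$lesion_id)), nf)
    cls <- classify_features(ft, alpha = alpha,
                             n_features = if (is.null(n_feats_bonf)) nf else
                               n_feats_bonf,
                             method = method)
    say("  gaussian pre/post/never: %d/%d/%d", cls$counts[1L],
        cls$counts[2L], cls$counts[3L])
    resolved[[ids[i]]] <- ft
    classified[[ids[i]]] <- cls
    icc_rc[[paste0(ids[i], "_original")]] <-
      .dataset_icc_rc(ft, cls$records, paste0(ids[i], "_original"),
                      d$sequence, isTRUE(d$normalised), "original")
    icc_rc[[paste0(ids[i], "_boxcox")]] <-
      .dataset_icc_rc(cls$table, cls$records, paste0(ids[i], "_boxcox"),
                      d$sequence, isTRUE(d$normalised), "boxcox")
  }
  icc_rc <- do.call(rbind, icc_rc)
  rownames(icc_rc) <- NULL

  n_bonf <- if (is.null(n_feats_bonf)) {
    length(unique(icc_rc$feature))
  } else n_feats_bonf

  ## Table-1-style transformation counts
  counts <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    cc <- classified[[ids[i]]]$counts
    data.frame(sequence = datasets[[i]]$sequence,
               normalised = isTRUE(datasets[[i]]$normalised),
               gaussian_pre = cc[["gaussian_pre"]],
               gaussian_post = cc[["gaussian_post"]],
               never = cc[["never"]],
               stringsAsFactors = FALSE)
  }))

  ## pair-wise Fisher-Z comparisons
  lookup <- function(ds_id) {
    sub <- icc_rc[icc_rc$dataset == ds_id, , drop = FALSE]
    setNames(split(sub, seq_len(nrow(sub))), sub$feature)
  }
  compare_pair <- function(label, id_a, id_b) {
    ta <- lookup(id_a); tb <- lookup(id_b)
    feats <- intersect(names(ta), names(tb))
    rows <- lapply(feats, function(f) {
      ra <- ta[[f]]; rb <- tb[[f]]
      if (abs(ra$icc) >= 1 || abs(rb$icc) >= 1) return(NULL)
      a_res <- structure(list(icc = ra$icc, n = ra$n), class = "icc_result")
      b_res <- structure(list(icc = rb$icc, n = rb$n), class = "icc_result")
      cmp <- compare_iccs(a_res, b_res, alpha = alpha, n_features = n_bonf)
      data.frame(comparison = label, dataset_a = id_a, dataset_b = id_b,
                 feature = f, z_diff = cmp$z_diff, ci_low = cmp$ci_low,
                 ci_high = cmp$ci_high, p = cmp$p,
                 significant = cmp$significant, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  }

  comparisons <- list()
  # effect of the Box-Cox transformation, per dataset
  for (id in ids) {
    comparisons[[paste0("boxcox_effect:", id)]] <-
      compare_pair(paste0("boxcox_effect:", id),
                   paste0(id, "_boxcox"), paste0(id, "_original"))
  }
  # sequence pairs at matching normalisation, Box-Cox variant
  seqs <- vapply(datasets, `[[`, character(1L), "sequence")
  norms <- vapply(datasets, function(d) isTRUE(d$normalised), logical(1L))
  for (nrm in unique(norms)) {
    present <- which(norms == nrm)
    if (length(present) < 2L) next
    for (ia in present) for (ib in present) {
      if (ia >= ib) next
      label <- sprintf("sequence:%s_vs_%s_%s", seqs[ia], seqs[ib],
                       if (nrm) "norm" else "raw")
      comparisons[[label]] <- compare_pair(label,
                                           paste0(ids[ia], "_boxcox"),
                                           paste0(ids[ib], "_boxcox"))
    }
  }
  # normalisation effect per sequence, Box-Cox variant
  for (sq in unique(seqs)) {
    has_raw <- which(seqs == sq & !norms)
    has_norm <- which(seqs == sq & norms)
    if (length(has_raw) == 1L && length(has_norm) == 1L) {
      label <- paste0("normalisation:", sq)
      comparisons[[label]] <- compare_pair(label,
                                           paste0(ids[has_norm], "_boxcox"),
                                           paste0(ids[has_raw], "_boxcox"))
    }
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  comparison_summary <- if (!is.null(comparisons)) {
    agg <- aggregate(significant ~ comparison, data = comparisons, FUN = sum)
    tot <- aggregate(significant ~ comparison, data = comparisons,
                     FUN = length)
    data.frame(comparison = agg$comparison, n_significant = agg$significant,
               n_features = tot$significant, stringsAsFactors = FALSE)
  } else NULL

  ## CoV of ICCs across the Box-Cox datasets (one per sequence x norm)
  bc <- icc_rc[icc_rc$variant == "boxcox", , drop = FALSE]
  cov_tab <- do.call(rbind, lapply(split(bc, bc$feature), function(sub) {
    if (nrow(sub) < 2L) return(NULL)
    data.frame(feature = sub$feature[1L], n_datasets = nrow(sub),
               cov = icc_cov_across_datasets(sub$icc),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cov_tab)) rownames(cov_tab) <- NULL

  n_sig <- if (!is.null(comparisons)) sum(comparisons$significant) else 0L
  say("%d dataset combinations, %d comparisons (%d significant)",
      length(unique(icc_rc$dataset)),
      if (is.null(comparisons)) 0L else nrow(comparisons), n_sig)

  structure(list(icc_rc = icc_rc,
                 transformation_counts = counts,
                 comparisons = comparisons,
                 comparison_summary = comparison_summary,
                 cov = cov_tab,
                 median_bins = median_bins,
                 provenance = list(seed = seed, alpha = alpha,
                                   bin_width = bin_width,
                                   boxcox_method = method,
                                   n_features_bonferroni = n_bonf,
                                   package_version =
                                     as.character(packageVersion("radrep")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d dataset combinations, %d feature estimates\n",
              length(unique(x$icc_rc$dataset)), nrow(x$icc_rc)))
  print(x$transformation_counts)
  invisible(x)
}

#' Write a study report as delimited text
#'
#' Serialises every table of a [run_study()] report to tab-separated files
#' plus a JSON provenance record, writing each file atomically (temp file +
#' rename). Numbers are written at full precision.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atomically <- function(obj, name) {
    path <- file.path(dir, name)
    tmp <- paste0(path, ".tmp")
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      write.table(obj, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    file.rename(tmp, path)
    path
  }
  paths <- c(atomically(report$icc_rc, "icc_rc.tsv"),
             atomically(report$transformation_counts,
                        "transformation_counts.tsv"))
  if (!is.null(report$comparisons)) {
    paths <- c(paths, atomically(report$comparisons, "comparisons.tsv"),
               atomically(report$comparison_summary,
                          "comparison_summary.tsv"))
  }
  if (!is.null(report$cov)) {
    paths <- c(paths, atomically(report$cov, "icc_cov.tsv"))
  }
  paths <- c(paths, atomically(report$median_bins, "median_bins.tsv"),
             atomically(report$provenance, "provenance.json"))
  invisible(paths)
}
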