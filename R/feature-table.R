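#' Two-visit feature tables
#'
#' A feature table is the central exchange object of the package: a long-form
#' `data.frame` with columns `lesion_id`, `visit`, `feature`, `value`, holding
#' one row per (lesion, visit, feature). Lesions are the sampling units of the
#' repeatability analysis; visits index repeat measurements under identical
#' conditions.
#'
#' @param x a `data.frame` with columns `lesion_id`, `visit`, `feature`,
#'   `value` (extra columns are preserved but ignored by the analysis).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x) {
  required <- c("lesion_id", "visit", "feature", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x$lesion_id <- as.character(x$lesion_id)
  x$visit <- as.integer(x$visit)
  x$feature <- as.character(x$feature)
  x$value <- as.numeric(x$value)
  key <- paste(x$lesion_id, x$visit, x$feature, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (lesion, visit, feature) entry: (%s, %d, %s)",
                 dup$lesion_id, dup$visit, dup$feature))
  }
  class(x) <- c("feature_table", "data.frame")
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d lesions x %d visits x %d features\n",
              length(unique(x$lesion_id)), length(unique(x$visit)),
              length(unique(x$feature))))
  NextMethod()
}

#' List features present in a feature table
#' @param ft a [feature_table()].
#' @return Character vector of feature names.
#' @export
ft_features <- function(ft) sort(unique(ft$feature))

#' Lesion-by-visit matrix for one feature
#'
#' Pivots one feature of a table into the n x k matrix consumed by
#' [icc_1_1()] and [rc()]. Only lesions with a value at every visit are
#' retained (complete-case, paired analysis).
#'
#' @param ft a [feature_table()].
#' @param feature feature name.
#' @return Numeric matrix, rows = lesions (rownames = lesion ids),
#'   columns = visits.
#' @export
ft_matrix <- function(ft, feature) {
  sub <- ft[ft$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0L) stop("feature not present in table: ", feature)
  visits <- sort(unique(sub$visit))
  lesions <- sort(unique(sub$lesion_id))
  m <- matrix(NA_real_, length(lesions), length(visits),
              dimnames = list(lesions, paste0("visit", visits)))
  m[cbind(match(sub$lesion_id, lesions), match(sub$visit, visits))] <- sub$value
  m[complete.cases(m), , drop = FALSE]
}

#' Drop lesions that are not present at every visit
#'
#' The repeatability design is paired: a lesion contributes only if it was
#' measured at all visits. Unpaired lesions are removed with a warning naming
#' them.
#'
#' @param ft a [feature_table()].
#' @return A [feature_table()] restricted to fully paired lesions.
#' @export
ft_pair_visits <- function(ft) {
  visits <- sort(unique(ft$visit))
  tab <- table(ft$lesion_id, ft$visit)
  complete <- rownames(tab)[apply(tab > 0L, 1L, all)]
  dropped <- setdiff(unique(ft$lesion_id), complete)
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped),
            " lesion(s) without data at every visit: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  feature_table(ft[ft$lesion_id %in% complete, , drop = FALSE])
}

#' Convert a feature table between long and wide form
#'
#' Wide form has one row per (lesion, visit) and one column per feature.
#'
#' @param ft a [feature_table()].
#' @return `ft_widen`: a `data.frame` with columns `lesion_id`, `visit`, then
#'   one column per feature. `ft_lengthen`: a [feature_table()].
#' @export
ft_widen <- function(ft) {
  feats <- ft_features(ft)
  keys <- unique(ft[, c("lesion_id", "visit")])
  keys <- keys[order(keys$lesion_id, keys$visit), , drop = FALSE]
  rownames(keys) <- NULL
  out <- keys
  rowkey <- paste(ft$lesion_id, ft$visit, sep = "\r")
  outkey <- paste(keys$lesion_id, keys$visit, sep = "\r")
  for (f in feats) {
    sel <- ft$feature == f
    col <- rep(NA_real_, nrow(keys))
    col[match(rowkey[sel], outkey)] <- ft$value[sel]
    out[[f]] <- col
  }
  out
}

#' @param wide a wide-form `data.frame` as produced by [ft_widen()].
#' @rdname ft_widen
#' @export
ft_lengthen <- function(wide) {
  feats <- setdiff(names(wide), c("lesion_id", "visit"))
  long <- do.call(rbind, lapply(feats, function(f) {
    data.frame(lesion_id = wide$lesion_id, visit = wide$visit,
               feature = f, value = wide[[f]], stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  feature_table(long)
}

#' Read and write feature tables as delimited text
#'
#' Long form uses tab-separated columns `lesion_id`, `visit`, `feature`,
#' `value`; wide form has key columns `lesion_id`, `visit` and one column per
#' feature. `read_feature_tables()` accepts one or several files (e.g. one per
#' visit), detects the form, concatenates, validates uniqueness, and enforces
#' visit pairing.
#'
#' @param paths character vector of file paths.
#' @param pair drop lesions missing a visit (default `TRUE`).
#' @return A validated [feature_table()].
#' @export
read_feature_tables <- function(paths, pair = TRUE) {
  parts <- lapply(paths, function(p) {
    df <- tryCatch(read.delim(p, stringsAsFactors = FALSE,
                              check.names = FALSE, comment.char = "#"),
                   error = function(e) stop("malformed table '", p, "': ",
                                            conditionMessage(e)))
    long_form <- all(c("lesion_id", "visit", "feature", "value") %in% names(df))
    wide_form <- all(c("lesion_id", "visit") %in% names(df)) && !long_form
    if (!long_form && !wide_form) {
      stop("file '", p, "' has neither long-form columns ",
           "(lesion_id, visit, feature, value) nor wide-form keys ",
           "(lesion_id, visit)")
    }
    bad <- if (long_form) which(is.na(suppressWarnings(as.numeric(df$value))) &
                                  !is.na(df$value)) else integer(0)
    if (length(bad) > 0L) {
      stop("file '", p, "': non-numeric value at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (wide_form) df <- ft_lengthen(df)
    df[, c("lesion_id", "visit", "feature", "value")]
  })
  ft <- feature_table(do.call(rbind, parts))
  if (pair) ft <- ft_pair_visits(ft)
  ft
}

#' @param ft a [feature_table()].
#' @param path output file path.
#' @param form `"long"` or `"wide"`.
#' @param provenance prepend `#`-commented provenance lines (class and
#'   formula per feature, from [feature_provenance()]) for the features
#'   present in the table.
#' @rdname read_feature_tables
#' @export
write_feature_table <- function(ft, path, form = c("long", "wide"),
                                provenance = FALSE) {
  form <- match.arg(form)
  out <- if (form == "wide") ft_widen(ft) else as.data.frame(ft)
  con <- file(path, "w")
  on.exit(close(con))
  if (provenance) {
    prov <- feature_provenance()
    prov <- prov[prov$feature %in% ft_features(ft), , drop = FALSE]
    writeLines(sprintf("# %s\t%s\t%s\t%s", prov$feature, prov$class,
                       prov$formula, prov$parameters), con)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
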