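#' Construct a detection history
#'
#' A detection history is the observational unit of a single-season occupancy
#' analysis: a sites x occasions matrix whose entries record detection (1),
#' non-detection (0) or a missed visit (`NA`). Rows are sites, columns are
#' sampling occasions.
#'
#' @param matrix Integer (or coercible) matrix with entries in \{0, 1, NA\}.
#' @param site_ids Character vector of unique site identifiers, one per row.
#'   Defaults to the matrix rownames, or `site_1 ... site_S`.
#' @param occasion_labels Character vector of unique occasion labels, one per
#'   column. Defaults to the matrix colnames, or `occ_1 ... occ_K`.
#' @return An object of class `detection_history`: a list with elements
#'   `matrix`, `site_ids`, `occasion_labels`.
#' @examples
#' m <- rbind(c(1, 0, NA), c(0, 0, 0))
#' detection_history(m, site_ids = c("A", "B"))
#' @export
detection_history <- function(matrix, site_ids = NULL, occasion_labels = NULL) {
  m <- as.matrix(matrix)
  if (is.null(site_ids)) {
    site_ids <- rownames(m)
    if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(nrow(m)))
  }
  if (is.null(occasion_labels)) {
    occasion_labels <- colnames(m)
    if (is.null(occasion_labels)) occasion_labels <- paste0("occ_", seq_len(ncol(m)))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(site_ids, occasion_labels)
  x <- structure(
    list(matrix = m, site_ids = as.character(site_ids),
         occasion_labels = as.character(occasion_labels)),
    class = "detection_history"
  )
  validate_history(x, require_visits = FALSE)
}

#' Validate a detection history
#'
#' Checks the invariants every downstream routine assumes: entries are exactly
#' 0, 1 or `NA`; site ids and occasion labels are unique; every site retains
#' at least one actual visit.
#'
#' @param x A `detection_history`.
#' @param require_visits If `TRUE` (default) a site with no observed visits is
#'   an error. Model fitting requires this; pooling inputs do not (a tagged
#'   bromeliad may be unobserved in a period when its neighbours were
#'   surveyed), so the pooling routine relaxes it for its inputs and
#'   re-validates the pooled result in full.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_history <- function(x, require_visits = TRUE) {
  stopifnot(inherits(x, "detection_history"))
  m <- x$matrix
  if (nrow(m) != length(x$site_ids) || ncol(m) != length(x$occasion_labels))
    stop("matrix dimensions do not match site_ids / occasion_labels")
  bad <- !is.na(m) & !(m %in% c(0L, 1L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid detection value at site '%s', occasion '%s': must be 0, 1 or NA",
                 x$site_ids[idx[1]], x$occasion_labels[idx[2]]))
  }
  if (anyDuplicated(x$site_ids))
    stop("duplicate site id: ", x$site_ids[duplicated(x$site_ids)][1])
  if (anyDuplicated(x$occasion_labels))
    stop("duplicate occasion label: ",
         x$occasion_labels[duplicated(x$occasion_labels)][1])
  if (require_visits && any(rowSums(!is.na(m)) == 0))
    stop("site(s) with no observed visits: ",
         paste(x$site_ids[rowSums(!is.na(m)) == 0], collapse = ", "))
  x
}

#' @export
print.detection_history <- function(x, ...) {
  m <- x$matrix
  cat(sprintf("Detection history: %d sites x %d occasions\n", nrow(m), ncol(m)))
  cat(sprintf("  detections: %d | non-detections: %d | missing visits: %d\n",
              sum(m == 1L, na.rm = TRUE), sum(m == 0L, na.rm = TRUE), sum(is.na(m))))
  cat(sprintf("  naive occupancy: %.3f\n", naive_occupancy(x)))
  invisible(x)
}

#' Naive occupancy
#'
#' Fraction of sites with at least one detection, uncorrected for imperfect
#' detection. Always a lower bound (in expectation) on true occupancy.
#'
#' @param x A `detection_history`.
#' @return A proportion in \[0, 1\].
#' @export
naive_occupancy <- function(x) {
  stopifnot(inherits(x, "detection_history"))
  mean(rowSums(x$matrix == 1L, na.rm = TRUE) > 0)
}

#' Read a detection history from CSV
#'
#' Expects a header `site,<occ labels...>` with one row per site and cells in
#' \{0, 1, NA\}. This is the same format [write_history()] emits, and the two
#' round-trip exactly.
#'
#' @param path Path to a delimited text file.
#' @return A validated `detection_history`.
#' @export
read_history <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = "NA")
  if (ncol(df) < 2) stop("history file needs a site column plus >=1 occasion column")
  site_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  parsed <- suppressWarnings(matrix(as.integer(vals), nrow = nrow(vals)))
  bad <- (!is.na(vals) & is.na(parsed)) | (!is.na(parsed) & !(parsed %in% c(0L, 1L)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("cannot parse cell at row %d ('%s'), column '%s': value '%s' is not 0, 1 or NA",
                 idx[1], site_ids[idx[1]], colnames(vals)[idx[2]], vals[idx[1], idx[2]]))
  }
  validate_history(
    detection_history(parsed, site_ids = site_ids,
                      occasion_labels = colnames(vals)))
}

#' Write a detection history to CSV
#'
#' Deterministic writer: fixed column order `site,<occasions>`, missing visits
#' encoded as `NA`.
#'
#' @param x A `detection_history`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(x, path) {
  validate_history(x, require_visits = FALSE)
  df <- data.frame(site = x$site_ids, x$matrix, check.names = FALSE)
  colnames(df) <- c("site", x$occasion_labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Pool tagged and neighbouring-bromeliad histories
#'
#' Collapses the records from a tagged site and its touching neighbours into a
#' single patch-level history: a detection in either record counts as a
#' detection for the patch. An observed non-detection is kept over a missing
#' visit (an observed absence is information); the entry is missing only when
#' both records missed the visit.
#'
#' @param tagged,neighbour `detection_history` objects with identical
#'   `site_ids` and `occasion_labels`.
#' @return The pooled `detection_history`.
#' @examples
#' a <- detection_history(rbind(c(0, NA)), site_ids = "A")
#' b <- detection_history(rbind(c(1, 0)), site_ids = "A")
#' pool_tagged_and_neighbour(a, b)$matrix   # 1, 0
#' @export
pool_tagged_and_neighbour <- function(tagged, neighbour) {
  validate_history(tagged, require_visits = FALSE)
  validate_history(neighbour, require_visits = FALSE)
  if (!identical(tagged$site_ids, neighbour$site_ids) ||
      !identical(tagged$occasion_labels, neighbour$occasion_labels))
    stop("tagged and neighbour histories must share site_ids and occasion_labels")
  a <- tagged$matrix; b <- neighbour$matrix
  pooled <- pmax(a, b, na.rm = TRUE)          # NA only where both NA
  pooled[is.na(a) & is.na(b)] <- NA_integer_
  detection_history(pooled, site_ids = tagged$site_ids,
                    occasion_labels = tagged$occasion_labels)
}

#' Concatenate survey periods into one detection history
#'
#' Binds the occasion columns of several periods (e.g. monthly surveys) into a
#' single seasonal history, prefixing occasion labels with the period name.
#' Sites absent from a period (e.g. added between years) receive all-missing
#' columns for that period.
#'
#' @param histories Named list of `detection_history` objects, one per period,
#'   in chronological order. Unnamed lists get `p1, p2, ...` prefixes.
#' @return A single `detection_history` whose site set is the union of the
#'   inputs' sites (in order of first appearance).
#' @export
concat_periods <- function(histories) {
  stopifnot(is.list(histories), length(histories) >= 1)
  lapply(histories, validate_history, require_visits = FALSE)
  nm <- names(histories)
  if (is.null(nm) || any(nm == "")) nm <- paste0("p", seq_along(histories))
  all_sites <- unique(unlist(lapply(histories, `[[`, "site_ids")))
  blocks <- vector("list", length(histories))
  labels <- character(0)
  for (i in seq_along(histories)) {
    h <- histories[[i]]
    blk <- matrix(NA_integer_, nrow = length(all_sites), ncol = ncol(h$matrix))
    blk[match(h$site_ids, all_sites), ] <- h$matrix
    blocks[[i]] <- blk
    labels <- c(labels, paste(nm[i], h$occasion_labels, sep = "_"))
  }
  detection_history(do.call(cbind, blocks), site_ids = all_sites,
                    occasion_labels = labels)
}

#' Validate a site-covariate table
#'
#' One row per site of the paired history; columns are site-level covariates
#' (e.g. elevation in m a.s.l., altitudinal zone, bromeliad size, leaf and
#' neighbour counts).
#'
#' @param covs A data.frame with a `site` column.
#' @param history The paired `detection_history`.
#' @param elevation_range Optional length-2 numeric; if the table has an
#'   `elevation` column its values must fall inside this range.
#' @return `covs`, reordered to match `history$site_ids`.
#' @export
validate_site_covs <- function(covs, history, elevation_range = NULL) {
  stopifnot(is.data.frame(covs), "site" %in% names(covs))
  validate_history(history)
  if (anyDuplicated(covs$site)) stop("duplicate site in covariate table")
  if (!setequal(covs$site, history$site_ids))
    stop("site covariate table must have exactly one row per history site")
  covs <- covs[match(history$site_ids, covs$site), , drop = FALSE]
  rownames(covs) <- NULL
  counts <- intersect(c("n_leaves", "n_neighbours"), names(covs))
  for (cc in counts)
    if (any(covs[[cc]] < 0, na.rm = TRUE)) stop("negative count in ", cc)
  if (!is.null(elevation_range) && "elevation" %in% names(covs)) {
    e <- covs$elevation
    if (any(e < elevation_range[1] | e > elevation_range[2], na.rm = TRUE))
      stop("elevation outside declared range")
  }
  covs
}

#' Validate a survey-covariate table
#'
#' Long format, one row per site x occasion, keyed by `site` and `occ`
#' (occasion label). Covariates vary by visit: observer experience, minutes
#' after dusk, etc. A covariate may be missing only where the paired history
#' entry is itself a missed visit.
#'
#' @param covs A data.frame with `site` and `occ` columns.
#' @param history The paired `detection_history`.
#' @return `covs`, reordered to site-major, occasion-minor order covering every
#'   site x occasion cell of the history.
#' @export
validate_survey_covs <- function(covs, history) {
  stopifnot(is.data.frame(covs), all(c("site", "occ") %in% names(covs)))
  validate_history(history)
  key <- paste(covs$site, covs$occ, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate site x occasion row in survey covariates")
  full <- expand.grid(occ = history$occasion_labels, site = history$site_ids,
                      stringsAsFactors = FALSE)[, c("site", "occ")]
  idx <- match(paste(full$site, full$occ, sep = "\r"), key)
  if (anyNA(idx)) stop("survey covariates missing site x occasion cells present in the history")
  covs <- covs[idx, , drop = FALSE]
  rownames(covs) <- NULL
  observed <- !is.na(t(history$matrix))  # occasion-major per site == row order
  vars <- setdiff(names(covs), c("site", "occ"))
  for (v in vars) {
    if (any(is.na(covs[[v]]) & as.vector(observed)))
      stop("survey covariate '", v, "' missing at an observed visit")
  }
  covs
}
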