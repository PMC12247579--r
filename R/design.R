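#' Assemble a grouped design matrix
#'
#' Concatenates named feature blocks column-wise into a single design matrix
#' \code{X = [F_1, F_2, ..., F_J]} while recording which columns belong to
#' which group. Every downstream estimator in the package (EM-banded fits,
#' Ridge baselines) consumes this structure: the group partition determines
#' which regression weights share a prior variance scale.
#'
#' @param feature_blocks A named list of numeric matrices (or vectors, treated
#'   as single columns). All blocks must have the same number of rows. Block
#'   order is preserved; unnamed blocks are named \code{"F1"}, \code{"F2"}, ...
#'
#' @return An object of class \code{grouped_design}: a list with elements
#'   \code{X} (the M x D matrix), \code{groups} (data frame with \code{name},
#'   \code{start}, \code{end}, \code{size} — 1-based inclusive column ranges),
#'   \code{M} and \code{D}.
#'
#' @examples
#' gd <- make_grouped_design(list(
#'   acoustic = matrix(rnorm(40), 10, 4),
#'   phonetic = matrix(rnorm(20), 10, 2)
#' ))
#' gd$D            # 6
#' group_names(gd) # "acoustic" "phonetic"
#' @export
make_grouped_design <- function(feature_blocks) {
  if (!is.list(feature_blocks) || length(feature_blocks) == 0L)
    stop("'feature_blocks' must be a non-empty list of matrices", call. = FALSE)
  nms <- names(feature_blocks)
  if (is.null(nms)) nms <- rep("", length(feature_blocks))
  nms[nms == ""] <- paste0("F", seq_along(feature_blocks))[nms == ""]
  if (anyDuplicated(nms))
    stop("group names must be unique", call. = FALSE)

  blocks <- lapply(feature_blocks, function(b) {
    if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 1L)
    storage.mode(b) <- "double"
    b
  })
  rows <- vapply(blocks, nrow, integer(1))
  if (length(unique(rows)) != 1L) {
    bad <- nms[rows != rows[1L]][1L]
    stop(sprintf("block '%s' has %d rows; expected %d", bad,
                 rows[nms == bad][1L], rows[1L]), call. = FALSE)
  }
  sizes <- vapply(blocks, ncol, integer(1))
  if (any(sizes < 1L))
    stop("every feature block needs at least one column", call. = FALSE)
  X <- do.call(cbind, blocks)
  if (!all(is.finite(X)))
    stop("design matrix contains non-finite entries", call. = FALSE)
  colnames(X) <- NULL
  ends <- cumsum(sizes)
  groups <- data.frame(name = nms, start = ends - sizes + 1L, end = ends,
                       size = sizes, stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(X = X, groups = groups, M = unname(rows[1L]),
                 D = unname(ends[length(ends)])),
            class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat(sprintf("grouped_design: %d observations x %d predictors in %d group(s)\n",
              x$M, x$D, nrow(x$groups)))
  for (j in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: columns %d-%d (%d)\n", x$groups$name[j],
                x$groups$start[j], x$groups$end[j], x$groups$size[j]))
  invisible(x)
}

#' Group names of a grouped design
#' @param design A \code{grouped_design}.
#' @return Character vector of group names, in column order.
#' @export
group_names <- function(design) design$groups$name

#' Column indices of one group
#' @param design A \code{grouped_design}.
#' @param j Group index or name.
#' @return Integer vector of column indices into \code{design$X}.
#' @export
group_columns <- function(design, j) {
  if (is.character(j)) j <- match(j, design$groups$name)
  if (is.na(j) || j < 1L || j > nrow(design$groups))
    stop("unknown group", call. = FALSE)
  seq.int(design$groups$start[j], design$groups$end[j])
}

#' Center columns of a design matrix and target(s)
#'
#' The model carries no intercept: inputs and targets are centered instead,
#' and the stored means are reapplied at prediction time.
#'
#' @param X Numeric matrix.
#' @param y Numeric vector or matrix of targets (optional).
#' @return List with \code{X}, \code{y}, \code{x_means}, \code{y_means}.
#' @export
center_columns <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite entries", call. = FALSE)
  x_means <- colMeans(X)
  Xc <- sweep(X, 2L, x_means, "-")
  y_means <- NULL
  yc <- NULL
  if (!is.null(y)) {
    yv <- if (is.null(dim(y))) matrix(as.numeric(y), ncol = 1L) else as.matrix(y)
    if (!all(is.finite(yv))) stop("y contains non-finite entries", call. = FALSE)
    y_means <- colMeans(yv)
    yc <- sweep(yv, 2L, y_means, "-")
    if (is.null(dim(y))) yc <- drop(yc)
  }
  list(X = Xc, y = yc, x_means = x_means, y_means = y_means)
}

#' Build a time-lagged grouped design from a multichannel series
#'
#' Constructs the design matrix used in temporal response function (TRF)
#' analyses: every channel contributes one column per requested lag, and all
#' lag copies of a channel form one predictor group, so the fit can shrink an
#' entire (for example, noisy) channel across all its lags at once. Rows where
#' any lag would index outside the series are dropped (valid-sample
#' convention); the returned design records which rows of the input survive.
#'
#' @param series Numeric matrix, M time points x C channels (a vector is
#'   treated as one channel).
#' @param lags Integer vector of sample offsets; lag L places
#'   \code{series[t - L, c]} at output row t. Positive lags look back in time.
#' @return A \code{grouped_design} with \code{C * length(lags)} columns and an
#'   extra element \code{rows} giving the retained time indices.
#' @export
build_lagged_design <- function(series, lags) {
  if (is.null(dim(series))) series <- matrix(as.numeric(series), ncol = 1L)
  series <- as.matrix(series)
  M <- nrow(series); C <- ncol(series)
  lags <- as.integer(lags)
  if (length(lags) == 0L) stop("'lags' must be non-empty", call. = FALSE)
  if (any(abs(lags) >= M))
    stop("lag magnitude must be smaller than the series length", call. = FALSE)
  t_keep <- seq_len(M)
  t_keep <- t_keep[t_keep - max(lags, 0L) >= 1L & t_keep - min(lags, 0L) <= M]
  if (length(t_keep) == 0L)
    stop("no valid samples remain after lagging", call. = FALSE)
  ch_names <- colnames(series)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(C))
  blocks <- lapply(seq_len(C), function(cc) {
    out <- vapply(lags, function(L) series[t_keep - L, cc], numeric(length(t_keep)))
    matrix(out, ncol = length(lags))
  })
  names(blocks) <- ch_names
  gd <- make_grouped_design(blocks)
  gd$rows <- t_keep
  gd$lags <- lags
  gd
}
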