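#' Read a numeric matrix from delimited text
#'
#' @param path CSV or TSV file with a header row (delimiter inferred from the
#'   extension, or detected by the reader).
#' @return A numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is lossless for doubles.
#'
#' @param m Numeric matrix or vector.
#' @param path Output path (.csv or .tsv).
#' @export
write_matrix <- function(m, path) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L, dimnames = list(NULL, "y"))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(signif_chr(m))
  colnames(df) <- colnames(m)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_chr <- function(m) {
  out <- format(m, digits = 17, scientific = TRUE, trim = TRUE)
  dim(out) <- dim(m)
  out
}

#' Read a fitting configuration (YAML or JSON)
#'
#' Recognized keys: \code{groups} (list of entries with \code{name},
#' \code{n_columns}, optional \code{h}), either \code{gamma} or the four
#' hyperprior parameters \code{tau}/\code{eta}/\code{kappa}/\code{phi},
#' \code{max_iterations}, \code{tolerance}, \code{seed}.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return A list with elements \code{group_sizes} (named integer vector),
#'   \code{h} (named numeric vector or NULL), \code{hyper}
#'   (\code{hyperpriors}), \code{max_iter}, \code{tol}, \code{seed}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("config: missing 'groups'", call. = FALSE)
  gl <- cfg$groups
  if (is.data.frame(gl)) gl <- split(gl, seq_len(nrow(gl)))
  nms <- vapply(gl, function(g) as.character(g$name), character(1))
  sizes <- vapply(gl, function(g) {
    if (is.null(g$n_columns)) stop("config: group missing 'n_columns'",
                                   call. = FALSE)
    as.integer(g$n_columns)
  }, integer(1))
  hs <- vapply(gl, function(g) if (is.null(g$h)) NA_real_ else as.numeric(g$h),
               numeric(1))
  names(sizes) <- nms
  h <- if (all(is.na(hs))) NULL else stats::setNames(hs[!is.na(hs)],
                                                     nms[!is.na(hs)])
  hyper <- if (!is.null(cfg$gamma)) hyperpriors(gamma = as.numeric(cfg$gamma))
           else hyperpriors(eta = cfg$eta %||% 1e-4, tau = cfg$tau %||% 1e-4,
                            phi = cfg$phi %||% 1e-4, kappa = cfg$kappa %||% 1e-4)
  list(group_sizes = sizes, h = h, hyper = hyper,
       max_iter = as.integer(cfg$max_iterations %||% 200L),
       tol = as.numeric(cfg$tolerance %||% 1e-8),
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Partition the columns of a flat matrix into a grouped_design per config.
design_from_config <- function(X, group_sizes) {
  if (sum(group_sizes) != ncol(X))
    stop(sprintf("group sizes sum to %d but the matrix has %d columns",
                 sum(group_sizes), ncol(X)), call. = FALSE)
  ends <- cumsum(group_sizes)
  blocks <- lapply(seq_along(group_sizes), function(j)
    X[, seq.int(ends[j] - group_sizes[j] + 1L, ends[j]), drop = FALSE])
  names(blocks) <- names(group_sizes)
  make_grouped_design(blocks)
}

#' Write fitted weights as an annotated CSV
#'
#' One row per predictor column: \code{column}, \code{group}, \code{weight}
#' (one weight column per target for multi-target fits).
#'
#' @param fit An \code{em_banded} or \code{em_banded_multi} object.
#' @param path Output CSV path.
#' @export
write_weights_csv <- function(fit, path) {
  groups <- fit$groups
  group_of <- rep(groups$name, groups$size)
  W <- if (is.matrix(fit$weights)) fit$weights
       else matrix(fit$weights, ncol = 1L)
  wcols <- if (ncol(W) == 1L) "weight" else paste0("weight_", seq_len(ncol(W)))
  df <- data.frame(column = seq_along(group_of), group = group_of,
                   stringsAsFactors = FALSE)
  for (i in seq_along(wcols)) df[[wcols[i]]] <- signif_chr(W[, i])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fit hyperparameters and diagnostics as JSON
#'
#' @param fit An \code{em_banded}/\code{em_banded_multi} object.
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    lambdas = as.list(fit$lambdas), nu = fit$nu, n_iter = fit$n_iter,
    converged = fit$converged, objective_trace = fit$objective_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
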