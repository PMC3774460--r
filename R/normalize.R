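#' Tendency treatment: common bigger-is-better [0,1] scale
#'
#' Raw indicators point in different directions: for a benefit indicator a
#' higher value is better, for a cost indicator a lower value is better, and
#' for an interval indicator values inside a reference band are best.
#' Tendency treatment maps every column onto [0,1] so that 1 is always best:
#' \deqn{x'_{ij} = (x_{ij} - \min_j)/(\max_j - \min_j)}{(x - min)/(max - min)}
#' for benefit columns,
#' \deqn{x'_{ij} = (\max_j - x_{ij})/(\max_j - \min_j)}{(max - x)/(max - min)}
#' for cost columns, and for interval columns a score of 1 inside
#' `[low, high]` decaying linearly to 0 at the observed column extremes.
#'
#' @name tendency_treatment
NULL

#' Read a hospital indicator matrix from CSV
#'
#' First column `hospital_id`, remaining columns raw leaf-indicator values.
#'
#' @param path CSV path.
#' @return numeric matrix with hospital ids as rownames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix CSV needs hospital_id plus >= 1 indicator column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a hospital indicator matrix to CSV
#' @param m numeric matrix with hospital ids as rownames.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(hospital_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_matrix <- function(m, h) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(!nzchar(rownames(m)))) {
    stop("hospital matrix must have non-empty row ids", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("hospital matrix contains non-finite values", call. = FALSE)
  ids <- leaf_ids(h)
  if (!setequal(colnames(m), ids)) {
    stop("matrix columns do not match hierarchy leaves; missing: ",
         paste(setdiff(ids, colnames(m)), collapse = ", "),
         "; extra: ", paste(setdiff(colnames(m), ids), collapse = ", "),
         call. = FALSE)
  }
  m[, ids, drop = FALSE]
}

#' Interval bounds from column statistics
#'
#' Fallback "best interval" for an interval indicator without a published
#' reference band: mean +/- one sample standard deviation (denominator
#' n - 1) of the observed values.
#'
#' @param values numeric vector, length >= 2.
#' @return numeric `c(low, high)`.  All-equal input yields a zero-width
#'   interval with a warning.
#' @export
interval_bounds_from_stats <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) warning("degenerate zero-width interval: all values equal")
  mean(values) + c(-1, 1) * s
}

# Interval tendency score: 1 inside [low, high], linear decay to 0 at the
# observed extremes, clipped to [0, 1].
.interval_score <- function(x, low, high) {
  mn <- min(x); mx <- max(x)
  s <- rep(1, length(x))
  below <- x < low
  if (any(below)) {
    s[below] <- if (low > mn) 1 - (low - x[below]) / (low - mn) else 1
  }
  above <- x > high
  if (any(above)) {
    s[above] <- if (mx > high) 1 - (x[above] - high) / (mx - high) else 1
  }
  pmin(pmax(s, 0), 1)
}

#' Normalize a hospital matrix by indicator tendency
#'
#' Applies the benefit/cost/interval rules column by column.  Interval
#' columns use the hierarchy's reference band when present (a scalar target
#' is a zero-width band); otherwise the mean +/- sd fallback of
#' [interval_bounds_from_stats()].  A constant non-interval column cannot be
#' rescaled and maps to 1 everywhere (flagged in the `degenerate`
#' attribute): an indicator with no variation should not penalize anyone,
#' and entropy weighting assigns it no weight.
#'
#' @param m numeric hospitals x leaves matrix (>= 2 rows), columns named by
#'   leaf id.
#' @param h the `indicator_hierarchy` supplying attributes and references.
#' @return matrix of the same shape with values in [0,1], columns in
#'   hierarchy leaf order; attribute `degenerate` lists constant columns.
#' @export
normalize_matrix <- function(m, h) {
  m <- .check_matrix(m, h)
  if (nrow(m) < 2) stop("need >= 2 hospitals to normalize", call. = FALSE)
  lt <- leaf_table(h)
  out <- m
  degenerate <- character()
  for (j in seq_len(nrow(lt))) {
    x <- m[, lt$id[j]]
    attr_j <- lt$attribute[j]
    rng <- max(x) - min(x)
    if (attr_j == "interval") {
      ref <- lt$reference[[j]]
      b <- if (is.null(ref)) interval_bounds_from_stats(x)
           else if (length(ref) == 1) c(ref, ref) else ref
      if (rng == 0) {
        degenerate <- c(degenerate, lt$id[j])
        out[, lt$id[j]] <- rep(1, length(x))
      } else {
        out[, lt$id[j]] <- .interval_score(x, b[1], b[2])
      }
    } else if (rng == 0) {
      degenerate <- c(degenerate, lt$id[j])
      out[, lt$id[j]] <- rep(1, length(x))
    } else if (attr_j == "benefit") {
      out[, lt$id[j]] <- (x - min(x)) / rng
    } else {
      out[, lt$id[j]] <- (max(x) - x) / rng
    }
  }
  if (length(degenerate)) {
    warning("degenerate constant column(s) scored 1: ",
            paste(degenerate, collapse = ", "))
  }
  attr(out, "degenerate") <- degenerate
  out
}
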