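#' Weighted TOPSIS relative approach degree
#'
#' Classical Hwang-Yoon TOPSIS on the weighted, tendency-normalized decision
#' matrix.  Because tendency treatment already orients every column as
#' benefit ("bigger is better"), the ideal point is the column-wise maximum
#' of the weighted matrix `v_ij = w_j x'_ij` and the anti-ideal the
#' column-wise minimum.  Each hospital's relative approach degree is
#' \deqn{C_i = D^-_i / (D^+_i + D^-_i)}
#' with `D+`/`D-` the Euclidean distances to the ideal/anti-ideal points;
#' higher `C_i` is better.  No additional vector normalization is applied
#' before weighting: the inputs are already on a common [0,1] scale.
#'
#' @param nm normalized hospitals x indicators matrix (entries in [0,1]).
#' @param w weight vector aligned with the columns of `nm` (a `weight_set`
#'   or plain numeric); only relative magnitudes matter (`C_i` is invariant
#'   to rescaling all weights by a positive constant).
#' @return a `topsis_result`: data.frame with `hospital_id`, `C_i`,
#'   `D_plus`, `D_minus`, `rank` (1 = best; ties broken by input row order).
#' @export
weighted_topsis <- function(nm, w) {
  stopifnot(is.matrix(nm), is.numeric(nm), nrow(nm) >= 2)
  w <- as.numeric(w)
  if (length(w) != ncol(nm)) stop("weight length != number of columns", call. = FALSE)
  if (any(w <= 0) || any(!is.finite(w))) stop("weights must be positive and finite", call. = FALSE)
  v <- sweep(nm, 2, w, `*`)
  ideal <- apply(v, 2, max)
  anti  <- apply(v, 2, min)
  d_plus  <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, anti)^2))
  ci <- numeric(nrow(v))
  both_zero <- d_plus + d_minus == 0
  if (any(both_zero)) {
    warning("hospital(s) coincide with both ideal and anti-ideal (all columns constant); C_i set to 0.5")
    ci[both_zero] <- 0.5
  }
  ok <- !both_zero
  ci[ok] <- d_minus[ok] / (d_plus[ok] + d_minus[ok])
  # stable rank: descending C_i, ties keep input row order
  rk <- integer(length(ci))
  rk[order(-ci, seq_along(ci))] <- seq_along(ci)
  res <- data.frame(
    hospital_id = rownames(nm) %||% paste0("S", seq_len(nrow(nm))),
    C_i = ci, D_plus = d_plus, D_minus = d_minus, rank = rk,
    stringsAsFactors = FALSE)
  class(res) <- c("topsis_result", "data.frame")
  res
}

#' Ranked report table
#'
#' Rows sorted by rank (best first) with `C_i` rounded to 4 decimals for
#' display; the full-precision result object is left untouched.  Tied `C_i`
#' values keep their input order and are flagged in a `tie` column.
#'
#' @param r a `topsis_result`.
#' @return data.frame `hospital_id, C_i, rank, tie` sorted by rank.
#' @export
rank_table <- function(r) {
  stopifnot(inherits(r, "topsis_result"))
  out <- as.data.frame(r)[order(r$rank), c("hospital_id", "C_i", "rank")]
  out$tie <- duplicated(out$C_i) | duplicated(out$C_i, fromLast = TRUE)
  out$C_i <- round(out$C_i, 4)
  rownames(out) <- NULL
  out
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("weighted TOPSIS result,", nrow(x), "hospitals\n")
  print(rank_table(x))
  invisible(x)
}
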