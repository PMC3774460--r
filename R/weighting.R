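#' Weighting: AHP for levels 1-2, entropy weights for level 3
#'
#' Level-1 and level-2 weights are elicited from Saaty pairwise-comparison
#' matrices via the principal-eigenvector method with a consistency ratio
#' (CR) check; level-3 weights are data-driven entropy weights computed on
#' the tendency-normalized matrix.  Comprehensive leaf weights are the
#' product of the three levels.
#'
#' @name weighting
NULL

# Saaty random consistency indices, k = 1..15.
.SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
               1.51, 1.48, 1.56, 1.57, 1.59)

.check_pairwise <- function(P, tol = 1e-9) {
  stopifnot(is.matrix(P), is.numeric(P))
  k <- nrow(P)
  if (k != ncol(P) || k < 2 || k > 15) {
    stop("pairwise matrix must be square, size 2-15", call. = FALSE)
  }
  if (any(!is.finite(P)) || any(P <= 0)) {
    stop("pairwise matrix entries must be positive and finite", call. = FALSE)
  }
  if (any(abs(diag(P) - 1) > tol)) stop("pairwise diagonal must be 1", call. = FALSE)
  if (any(abs(P * t(P) - 1) > 1e-6)) {
    stop("pairwise matrix is not reciprocal (a_uv * a_vu != 1)", call. = FALSE)
  }
  invisible(k)
}

#' AHP priority vector and consistency ratio
#'
#' Computes the normalized principal eigenvector of a positive reciprocal
#' judgment matrix by power iteration (default) or the row geometric-mean
#' approximation, plus Saaty's consistency ratio
#' `CR = ((lambda_max - k)/(k - 1)) / RI(k)`.  `CR` is defined as 0 for
#' `k <= 2` (a 2x2 reciprocal matrix is always consistent).  A `CR > 0.1`
#' flags inconsistent judgments via `consistent = FALSE` and a warning, but
#' the weights are still returned.
#'
#' @param P square positive reciprocal matrix (Saaty 1-9 scale judgments).
#' @param method `"eigenvector"` (power iteration, tolerance 1e-10) or
#'   `"geometric"` (row geometric means).
#' @param cr_threshold consistency threshold, conventionally 0.1.
#' @return list with `weights` (sums to 1, named from `P`'s rownames),
#'   `lambda_max`, `cr`, `consistent`.
#' @export
ahp_weights <- function(P, method = c("eigenvector", "geometric"),
                        cr_threshold = 0.1) {
  method <- match.arg(method)
  k <- .check_pairwise(P)
  if (method == "eigenvector") {
    w <- rep(1 / k, k)
    for (iter in seq_len(1000L)) {
      w_new <- as.vector(P %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
      w <- w_new
    }
  } else {
    g <- apply(P, 1, function(r) exp(mean(log(r))))
    w <- g / sum(g)
  }
  # lambda_max from the Rayleigh-style mean of (Pw)_u / w_u
  lambda_max <- mean(as.vector(P %*% w) / w)
  cr <- if (k <= 2) 0 else ((lambda_max - k) / (k - 1)) / .SAATY_RI[k]
  if (!is.null(rownames(P))) names(w) <- rownames(P)
  consistent <- cr <= cr_threshold
  if (!consistent) {
    warning(sprintf("AHP consistency ratio %.3f exceeds %.2f: judgments are inconsistent",
                    cr, cr_threshold))
  }
  list(weights = w, lambda_max = lambda_max, cr = cr, consistent = consistent)
}

#' Read a pairwise-comparison matrix from CSV
#'
#' Square layout with a header row and a leading label column.
#'
#' @param path CSV path.
#' @return labelled numeric matrix.
#' @export
read_pairwise_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  P <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(P) <- "double"
  rownames(P) <- as.character(df[[1]])
  .check_pairwise(P)
  P
}

#' Entropy weights for one indicator group
#'
#' Shannon-entropy weighting on a tendency-normalized block `x'` (hospitals
#' in rows, the indicators of one level-2 sibling group in columns):
#' shares `p_ij = x'_ij / sum_i x'_ij`, entropy
#' `h_j = -(1/ln n) sum_i p_ij ln p_ij` with `0 ln 0 = 0` and `n` the number
#' of hospitals, and weights `w_j = (1 - h_j) / sum_j (1 - h_j)`.  An
#' indicator that varies more across hospitals has lower entropy and earns
#' more weight.
#'
#' Degenerate cases: a column summing to 0 carries no information and gets
#' `h_j = 1`; if every `h_j = 1` (all columns constant) the group falls back
#' to uniform weights.  Both are flagged in `$degenerate` with a warning.
#'
#' @param nm numeric matrix block, values >= 0 (post tendency treatment),
#'   >= 2 rows.
#' @return list with `weights` (sums to 1), `entropy` (`h_j`), `shares`
#'   (`p_ij` matrix), `degenerate` (character).
#' @export
entropy_weights <- function(nm) {
  stopifnot(is.matrix(nm), is.numeric(nm), nrow(nm) >= 2)
  if (any(nm < 0)) stop("entropy weighting requires non-negative values", call. = FALSE)
  n <- nrow(nm)
  degenerate <- character()
  p <- nm
  h <- numeric(ncol(nm))
  for (j in seq_len(ncol(nm))) {
    cs <- sum(nm[, j])
    if (cs == 0) {
      p[, j] <- NA_real_
      h[j] <- 1
      degenerate <- c(degenerate, colnames(nm)[j] %||% as.character(j))
      next
    }
    p[, j] <- nm[, j] / cs
    terms <- ifelse(p[, j] > 0, p[, j] * log(p[, j]), 0)
    h[j] <- -sum(terms) / log(n)
  }
  d <- 1 - h
  if (sum(d) <= 0) {
    degenerate <- unique(c(degenerate, "all-constant-group"))
    w <- rep(1 / ncol(nm), ncol(nm))
  } else {
    w <- d / sum(d)
  }
  names(w) <- names(h) <- colnames(nm)
  if (length(degenerate)) {
    warning("entropy weighting degenerate: ", paste(degenerate, collapse = ", "))
  }
  list(weights = w, entropy = h, shares = p, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble comprehensive weights from per-level weights
#'
#' Builds the leaf-level weight set `w(leaf) = w_L1 * w_L2 * w_L3` from an
#' AHP level-1 priority vector, per-level-1-branch AHP level-2 vectors, and
#' per-level-2-branch level-3 weights (typically entropy weights).  The
#' hierarchy supplies only the tree shape; its stored weights are ignored.
#'
#' @param h an `indicator_hierarchy` giving the tree shape and leaf order.
#' @param ahp_l1 numeric vector, one weight per level-1 node.
#' @param ahp_l2 list (one per level-1 node) of numeric vectors, one weight
#'   per level-2 child.
#' @param l3 list (one per level-1 node) of lists of numeric vectors, one
#'   weight per leaf of each level-2 node.
#' @return named `weight_set` in leaf order; sums to 1 when every input
#'   group sums to 1.
#' @export
assemble_weights <- function(h, ahp_l1, ahp_l2, l3) {
  stopifnot(inherits(h, "indicator_hierarchy"))
  if (length(ahp_l1) != length(h$level1)) {
    stop("level-1 weight count ", length(ahp_l1), " != ", length(h$level1),
         " level-1 nodes", call. = FALSE)
  }
  w <- numeric(0)
  for (i in seq_along(h$level1)) {
    n1 <- h$level1[[i]]
    if (length(ahp_l2[[i]]) != length(n1$level2)) {
      stop("branch '", n1$name, "': level-2 weight count mismatch", call. = FALSE)
    }
    for (k in seq_along(n1$level2)) {
      n2 <- n1$level2[[k]]
      wl3 <- l3[[i]][[k]]
      if (length(wl3) != length(n2$leaves)) {
        stop("branch '", n1$name, "/", n2$name, "': level-3 weight count mismatch",
             call. = FALSE)
      }
      wk <- ahp_l1[i] * ahp_l2[[i]][k] * wl3
      names(wk) <- vapply(n2$leaves, `[[`, "", "id")
      w <- c(w, wk)
    }
  }
  structure(w, class = "weight_set")
}

#' Full hybrid weighting on a normalized matrix
#'
#' Convenience wrapper reproducing the published weighting scheme: level-1
#' and level-2 weights are taken from the hierarchy (or recomputed from
#' user-supplied AHP pairwise matrices), level-3 weights are entropy weights
#' computed per level-2 sibling group on the tendency-normalized matrix.
#'
#' @param nm normalized hospitals x leaves matrix from [normalize_matrix()].
#' @param h an `indicator_hierarchy`.
#' @param pairwise_l1 optional pairwise matrix for the level-1 group.
#' @param pairwise_l2 optional list (one per level-1 node, or named by node)
#'   of pairwise matrices for the level-2 groups.
#' @return named `weight_set` over the 41 (or however many) leaves.
#' @export
hybrid_weights <- function(nm, h, pairwise_l1 = NULL, pairwise_l2 = NULL) {
  stopifnot(inherits(h, "indicator_hierarchy"))
  if (is.null(pairwise_l1)) {
    wl1 <- vapply(h$level1, `[[`, 0, "weight")
  } else {
    wl1 <- ahp_weights(pairwise_l1)$weights
  }
  wl2 <- vector("list", length(h$level1))
  for (i in seq_along(h$level1)) {
    n1 <- h$level1[[i]]
    P <- if (is.null(pairwise_l2)) NULL
         else pairwise_l2[[n1$name]] %||% pairwise_l2[[i]]
    wl2[[i]] <- if (is.null(P)) vapply(n1$level2, `[[`, 0, "weight")
                else ahp_weights(P)$weights
  }
  l3 <- vector("list", length(h$level1))
  for (i in seq_along(h$level1)) {
    n1 <- h$level1[[i]]
    l3[[i]] <- vector("list", length(n1$level2))
    for (k in seq_along(n1$level2)) {
      ids <- vapply(n1$level2[[k]]$leaves, `[[`, "", "id")
      blk <- nm[, ids, drop = FALSE]
      l3[[i]][[k]] <- suppressWarnings(entropy_weights(blk)$weights)
    }
  }
  assemble_weights(h, wl1 / sum(wl1),
                   lapply(wl2, function(v) v / sum(v)), l3)
}
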