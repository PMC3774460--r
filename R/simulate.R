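#' Synthetic hospital data
#'
#' The original administrative indicator matrix behind the Hubei case study
#' is not public, so the package ships a generator with the statistical
#' structure the analysis assumes: each hospital has a latent quality score
#' `q ~ N(0, 1)` and every leaf indicator is a monotone function of `q` plus
#' independent noise, oriented by the leaf's attribute.  Benefit leaves rise
#' with `q`, cost leaves fall with `q`, and interval leaves deviate from
#' their reference band by a magnitude that shrinks as `q` grows (better
#' hospitals sit inside the band) with a random deviation side.  Raw values
#' are affine-mapped into a plausible range seeded from the leaf's published
#' reference value where one exists, and unit-scaled otherwise.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_hospitals number of hospitals (default 14, the case-study size).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param beta per-indicator signal strength (scalar recycled over leaves, or
#'   one value per leaf), > 0.
#' @param noise_sd standard deviation of the idiosyncratic noise added to
#'   each standardized indicator (default 0.1 against a unit signal: a
#'   hospital tier whose indicators are strongly quality-driven).
#' @param nonlinear when `TRUE` (default) every third benefit/cost leaf
#'   responds to `q + 0.3 q|q|` instead of `q`: a signed-quadratic warp that
#'   keeps the response monotone in `q` but bends the indicator-to-score
#'   relationship away from a straight line.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_hospitals = 14, seed = 1L, beta = 1,
                       noise_sd = 0.1, nonlinear = TRUE) {
  stopifnot(n_hospitals >= 3, all(beta > 0), noise_sd >= 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_hospitals = as.integer(n_hospitals), seed = as.integer(seed),
                 beta = beta, noise_sd = noise_sd,
                 nonlinear = isTRUE(nonlinear)),
            class = "sim_config")
}

# plausible (center, scale) for a leaf, seeded from its reference value
.leaf_range <- function(lf) {
  ref <- lf$reference
  if (lf$attribute == "interval") {
    if (is.null(ref)) return(list(center = 1, scale = 0.3, halfwidth = 0.3))
    if (length(ref) == 2) {
      return(list(center = mean(ref), scale = (ref[2] - ref[1]) / 2,
                  halfwidth = (ref[2] - ref[1]) / 2))
    }
    return(list(center = ref, scale = 0.25 * abs(ref) + (ref == 0),
                halfwidth = 0.25 * abs(ref) + (ref == 0)))
  }
  if (is.null(ref)) return(list(center = 0, scale = 1))
  if (lf$attribute == "benefit") {
    # threshold "at least ref": population sits a little above it
    list(center = ref * 1.05, scale = abs(ref) * 0.06 + (ref == 0))
  } else {
    # threshold "at most ref": population sits a little below it
    list(center = ref * 0.9, scale = abs(ref) * 0.1 + (ref == 0))
  }
}

#' Simulate a hospital indicator matrix
#'
#' @param cfg a [sim_config()].
#' @param h a validated `indicator_hierarchy`.
#' @return list with `matrix` (hospitals x leaves, rownames `H1..HN`,
#'   columns in leaf order) and `quality` (the latent scores).
#' @export
simulate_hospitals <- function(cfg, h) {
  stopifnot(inherits(cfg, "sim_config"), inherits(h, "indicator_hierarchy"))
  lt <- leaf_table(h)
  n_leaf <- nrow(lt)
  beta <- rep_len(cfg$beta, n_leaf)
  N <- cfg$n_hospitals
  .with_seed(cfg$seed, {
    q <- stats::rnorm(N)
    # deviation magnitude of interval indicators: better hospitals sit closer
    # to (or inside) their reference band
    mag <- exp(-0.8 * q)
    m <- matrix(NA_real_, N, n_leaf,
                dimnames = list(paste0("H", seq_len(N)), lt$id))
    mono_seen <- 0L
    for (j in seq_len(n_leaf)) {
      lf <- list(attribute = lt$attribute[j], reference = lt$reference[[j]])
      rng <- .leaf_range(lf)
      eps <- stats::rnorm(N, 0, cfg$noise_sd)
      if (lf$attribute == "interval") {
        side <- sample(c(-1, 1), N, replace = TRUE)
        m[, j] <- rng$center + rng$halfwidth * (1.3 * mag * side + eps)
      } else {
        mono_seen <- mono_seen + 1L
        s <- if (cfg$nonlinear && mono_seen %% 3L == 0L) q + 0.3 * q * abs(q) else q
        sgn <- if (lf$attribute == "benefit") 1 else -1
        m[, j] <- rng$center + rng$scale * (sgn * beta[j] * s + eps)
      }
    }
    list(matrix = m, quality = q)
  })
}

#' Simulate an AHP pairwise-comparison matrix around target weights
#'
#' Builds `a_uv = (w_u / w_v) exp(eta_uv)` with `eta_uv ~ N(0, sd^2)` drawn
#' for `u < v` only and mirrored as `a_vu = 1/a_uv`, so the matrix is always
#' exactly reciprocal.  `sd = 0` gives a perfectly consistent matrix from
#' which [ahp_weights()] recovers `w` with consistency ratio 0.
#'
#' @param w positive target weight vector (length 2-15).
#' @param sd log-scale perturbation standard deviation.
#' @param seed integer seed.
#' @return labelled positive reciprocal matrix.
#' @export
simulate_pairwise <- function(w, sd = 0, seed = 1L) {
  stopifnot(all(w > 0), length(w) >= 2, length(w) <= 15, sd >= 0)
  k <- length(w)
  .with_seed(seed, {
    P <- matrix(1, k, k)
    for (u in seq_len(k - 1)) for (v in seq((u + 1), k)) {
      a <- (w[u] / w[v]) * exp(stats::rnorm(1, 0, sd))
      P[u, v] <- a
      P[v, u] <- 1 / a
    }
    labs <- names(w) %||% paste0("item", seq_len(k))
    dimnames(P) <- list(labs, labs)
    P
  })
}

#' The packaged default synthetic fixture
#'
#' The 14-hospital, 41-indicator regression fixture every stage is exercised
#' on: the packaged hierarchy plus [simulate_hospitals()] under the default
#' [sim_config()] (seed 42 unless overridden).
#'
#' @param seed generator seed (default 42, the frozen fixture).
#' @param ... overrides passed to [sim_config()].
#' @return list `hierarchy`, `matrix`, `quality`, `config`.
#' @export
default_fixture <- function(seed = 42L, ...) {
  h <- hubei_hierarchy()
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_hospitals(cfg, h)
  list(hierarchy = h, matrix = sim$matrix, quality = sim$quality, config = cfg)
}
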