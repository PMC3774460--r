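# shared in-code fixtures: tiny hierarchies and random generators

# one level-1 / one level-2 hierarchy around a given leaf layout
mini_hierarchy <- function(attrs, refs = vector("list", length(attrs)),
                           weights = rep(1 / length(attrs), length(attrs))) {
  leaves <- lapply(seq_along(attrs), function(i) {
    list(id = paste0("x", i), name = paste0("leaf ", i), weight = weights[i],
         attribute = attrs[i], reference = refs[[i]], unit = "")
  })
  doc <- list(name = "mini", level1 = list(list(
    name = "L1", weight = 1,
    level2 = list(list(name = "L2", weight = 1, leaves = leaves)))))
  load_hierarchy(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                  digits = NA))
}

# random full-precision hierarchy: every sibling group sums to exactly 1
random_hierarchy <- function(seed) {
  set.seed(seed)
  rw <- function(k) { w <- runif(k, 0.2, 1); w / sum(w) }
  counter <- 0L
  l1w <- rw(sample(2:4, 1))
  doc <- list(name = "random", level1 = lapply(seq_along(l1w), function(i) {
    l2w <- rw(sample(1:3, 1))
    list(name = paste0("A", i), weight = l1w[i],
         level2 = lapply(seq_along(l2w), function(k) {
           l3w <- rw(sample(1:4, 1))
           list(name = paste0("A", i, "B", k), weight = l2w[k],
                leaves = lapply(seq_along(l3w), function(m) {
                  counter <<- counter + 1L
                  list(id = paste0("leaf", counter), name = "leaf",
                       weight = l3w[m],
                       attribute = sample(c("+", "-", "0"), 1),
                       reference = NULL, unit = "")
                }))
         }))
  }))
  load_hierarchy(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                  digits = NA), tol = 1e-9)
}

# matrix with named rows/cols for a mini hierarchy
named_matrix <- function(vals, n_leaf) {
  m <- matrix(vals, ncol = n_leaf)
  dimnames(m) <- list(paste0("H", seq_len(nrow(m))),
                      paste0("x", seq_len(n_leaf)))
  m
}
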