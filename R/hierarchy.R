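#' Indicator hierarchies
#'
#' A three-level indicator system: level-1 dimensions (e.g. Input, Process,
#' Output, Effect), level-2 sub-dimensions, and level-3 leaf indicators.
#' Each node carries a weight; within every sibling group the weights are
#' expected to sum to 1.  Leaves additionally carry an *attribute* that
#' drives tendency treatment: `"benefit"` (higher is better), `"cost"`
#' (lower is better) or `"interval"` (values inside a reference interval are
#' best), plus an optional reference value (a scalar threshold/target or an
#' ordered `[low, high]` pair) and a free-text unit.
#'
#' @name indicator_hierarchy
NULL

.ATTR_CODES <- c("+" = "benefit", "-" = "cost", "0" = "interval")

#' Load an indicator hierarchy from a JSON configuration
#'
#' The configuration schema is
#' `{level1: [{name, weight, level2: [{name, weight, leaves: [{id, name,
#' weight, attribute: "+"|"-"|"0", reference, unit}]}]}]}`.
#' `reference` may be `null`, a scalar, or a two-element `[low, high]` array.
#'
#' @param path path to a JSON document, or a raw JSON string.
#' @param tol sibling-group weight-sum tolerance passed to
#'   [validate_hierarchy()].  The packaged configuration stores weights
#'   rounded to two decimals, so the default allows |sum - 1| <= 0.01.
#' @return an object of class `indicator_hierarchy`.
#' @seealso [hubei_hierarchy()] for the packaged 4/11/41 configuration.
#' @export
load_hierarchy <- function(path, tol = 0.01) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed hierarchy document: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(doc$level1) || !length(doc$level1)) {
    stop("malformed hierarchy document: missing 'level1' array", call. = FALSE)
  }
  l1 <- lapply(doc$level1, function(n1) {
    .require_fields(n1, c("name", "weight"), "level-1 node")
    l2 <- lapply(n1$level2, function(n2) {
      .require_fields(n2, c("name", "weight"), paste0("level-2 node under '", n1$name, "'"))
      leaves <- lapply(n2$leaves, function(lf) {
        .require_fields(lf, c("id", "name", "weight", "attribute"),
                        paste0("leaf under '", n2$name, "'"))
        code <- as.character(lf$attribute)
        if (!code %in% names(.ATTR_CODES)) {
          stop("leaf '", lf$id, "': unknown attribute code '", code,
               "' (expected one of +, -, 0)", call. = FALSE)
        }
        ref <- lf$reference
        if (!is.null(ref)) ref <- as.numeric(unlist(ref))
        list(id = as.character(lf$id), name = as.character(lf$name),
             weight = as.numeric(lf$weight), attribute = unname(.ATTR_CODES[code]),
             reference = ref,
             unit = if (is.null(lf$unit)) "" else as.character(lf$unit))
      })
      list(name = as.character(n2$name), weight = as.numeric(n2$weight),
           leaves = leaves)
    })
    list(name = as.character(n1$name), weight = as.numeric(n1$weight), level2 = l2)
  })
  h <- structure(
    list(name = if (is.null(doc$name)) "" else as.character(doc$name), level1 = l1),
    class = "indicator_hierarchy")
  viol <- validate_hierarchy(h, tol = tol)
  if (length(viol)) {
    stop("invalid hierarchy:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  h
}

.require_fields <- function(node, fields, what) {
  missing <- setdiff(fields, names(node))
  if (length(missing)) {
    stop("malformed hierarchy document: ", what, " lacks field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' The packaged Hubei 4/11/41 hospital indicator system
#'
#' Loads the evaluation system used for the 14 level-3 public non-profit
#' hospitals in Hubei Province (first half of 2012): 4 level-1 dimensions
#' (Input, Process, Output, Effect), 11 level-2 sub-dimensions and 41 leaf
#' indicators, with the published AHP level-1/2 weights and entropy level-3
#' weights.  Published weights are rounded to two decimals, so sibling sums
#' are validated with a 0.01 tolerance.
#'
#' @return an `indicator_hierarchy` with 41 leaves.
#' @export
hubei_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "hubei_hierarchy.json",
                             package = "hospeval", mustWork = TRUE))
}

#' Validate an indicator hierarchy
#'
#' Checks: weights in (0, 1]; sibling-group weight sums within `tol` of 1;
#' unique leaf ids; interval references are ordered pairs (a scalar target is
#' treated as a zero-width interval); non-interval references are scalars.
#'
#' @param h an `indicator_hierarchy`.
#' @param tol allowed deviation of each sibling group's weight sum from 1.
#' @return character vector of violations; empty when the hierarchy is valid.
#' @export
validate_hierarchy <- function(h, tol = 0.01) {
  stopifnot(inherits(h, "indicator_hierarchy"))
  viol <- character()
  note <- function(...) viol[[length(viol) + 1L]] <<- paste0(...)
  chk_w <- function(w, what) {
    if (!is.finite(w) || w <= 0 || w > 1) note(what, ": weight must be positive and <= 1, got ", w)
  }
  chk_sum <- function(ws, what) {
    if (abs(sum(ws) - 1) > tol + 1e-9) {
      note(what, ": sibling weights sum to ", format(sum(ws)), ", expected 1 +/- ", tol)
    }
  }
  ids <- character()
  chk_sum(vapply(h$level1, `[[`, 0, "weight"), "level-1 group")
  for (n1 in h$level1) {
    chk_w(n1$weight, paste0("level-1 '", n1$name, "'"))
    if (!length(n1$level2)) { note("level-1 '", n1$name, "': no level-2 children"); next }
    chk_sum(vapply(n1$level2, `[[`, 0, "weight"), paste0("level-2 group under '", n1$name, "'"))
    for (n2 in n1$level2) {
      chk_w(n2$weight, paste0("level-2 '", n2$name, "'"))
      if (!length(n2$leaves)) { note("level-2 '", n2$name, "': no leaves"); next }
      chk_sum(vapply(n2$leaves, `[[`, 0, "weight"), paste0("leaf group under '", n2$name, "'"))
      for (lf in n2$leaves) {
        chk_w(lf$weight, paste0("leaf '", lf$id, "'"))
        ids <- c(ids, lf$id)
        r <- lf$reference
        if (lf$attribute == "interval") {
          if (!is.null(r)) {
            if (length(r) == 2 && r[1] > r[2]) {
              note("leaf '", lf$id, "': interval reference must satisfy low <= high")
            } else if (!length(r) %in% c(1, 2)) {
              note("leaf '", lf$id, "': interval reference must be scalar or [low, high]")
            }
          }
        } else if (!is.null(r) && length(r) != 1) {
          note("leaf '", lf$id, "': non-interval reference must be a scalar")
        }
      }
    }
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) note("duplicate leaf id(s): ", paste(dup, collapse = ", "))
  viol
}

#' Flatten a hierarchy to one row per leaf
#'
#' @param h an `indicator_hierarchy`.
#' @return a data.frame with columns `l1, l1_w, l2, l2_w, id, name, l3_w,
#'   attribute, reference, unit` in leaf order.  `reference` is a list
#'   column (`NULL`, scalar or length-2 numeric).
#' @export
leaf_table <- function(h) {
  stopifnot(inherits(h, "indicator_hierarchy"))
  rows <- list()
  for (n1 in h$level1) for (n2 in n1$level2) for (lf in n2$leaves) {
    rows[[length(rows) + 1L]] <- list(
      l1 = n1$name, l1_w = n1$weight, l2 = n2$name, l2_w = n2$weight,
      id = lf$id, name = lf$name, l3_w = lf$weight,
      attribute = lf$attribute, reference = list(lf$reference), unit = lf$unit)
  }
  out <- data.frame(
    l1 = vapply(rows, `[[`, "", "l1"), l1_w = vapply(rows, `[[`, 0, "l1_w"),
    l2 = vapply(rows, `[[`, "", "l2"), l2_w = vapply(rows, `[[`, 0, "l2_w"),
    id = vapply(rows, `[[`, "", "id"), name = vapply(rows, `[[`, "", "name"),
    l3_w = vapply(rows, `[[`, 0, "l3_w"),
    attribute = vapply(rows, `[[`, "", "attribute"),
    unit = vapply(rows, `[[`, "", "unit"),
    stringsAsFactors = FALSE)
  out$reference <- lapply(rows, function(r) r$reference[[1]])
  out
}

#' Leaf ids in hierarchy order
#' @param h an `indicator_hierarchy`.
#' @return character vector of leaf ids.
#' @export
leaf_ids <- function(h) leaf_table(h)$id

#' Comprehensive leaf weights
#'
#' The comprehensive weight of each leaf is the product of its level-1,
#' level-2 and level-3 weights.  When every sibling group sums to exactly 1
#' the comprehensive weights sum to exactly 1; with 2-dp published weights
#' the sum lands within about 1% of 1.
#'
#' @param h an `indicator_hierarchy`.
#' @return named numeric vector (class `weight_set`), one entry per leaf in
#'   hierarchy order.
#' @export
comprehensive_weights <- function(h) {
  lt <- leaf_table(h)
  w <- lt$l1_w * lt$l2_w * lt$l3_w
  names(w) <- lt$id
  structure(w, class = "weight_set")
}

#' Serialize a hierarchy back to the JSON configuration schema
#'
#' Inverse of [load_hierarchy()]: `load_hierarchy(serialize_hierarchy(h))`
#' reproduces `h`.
#'
#' @param h an `indicator_hierarchy`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
serialize_hierarchy <- function(h, path = NULL) {
  stopifnot(inherits(h, "indicator_hierarchy"))
  inv <- names(.ATTR_CODES); names(inv) <- unname(.ATTR_CODES)
  doc <- list(name = h$name, level1 = lapply(h$level1, function(n1) {
    list(name = n1$name, weight = n1$weight, level2 = lapply(n1$level2, function(n2) {
      list(name = n2$name, weight = n2$weight, leaves = lapply(n2$leaves, function(lf) {
        list(id = lf$id, name = lf$name, weight = lf$weight,
             attribute = unname(inv[lf$attribute]), reference = lf$reference,
             unit = lf$unit)
      }))
    }))
  }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Export a hierarchy as a flat CSV (one row per leaf)
#'
#' Columns `l1,l1_w,l2,l2_w,id,name,l3_w,attribute,reference,unit`;
#' `attribute` uses the `+`/`-`/`0` codes and an interval reference is
#' rendered `low;high`.
#'
#' @param h an `indicator_hierarchy`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
export_hierarchy_csv <- function(h, path) {
  lt <- leaf_table(h)
  inv <- names(.ATTR_CODES); names(inv) <- unname(.ATTR_CODES)
  lt$attribute <- unname(inv[lt$attribute])
  lt$reference <- vapply(lt$reference, function(r) {
    if (is.null(r)) "" else paste(format(r, trim = TRUE), collapse = ";")
  }, "")
  utils::write.csv(lt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  lt <- leaf_table(x)
  cat("indicator_hierarchy:", if (nzchar(x$name)) x$name else "<unnamed>", "\n")
  cat(sprintf("  %d level-1 / %d level-2 / %d leaves\n",
              length(x$level1), length(unique(paste(lt$l1, lt$l2))), nrow(lt)))
  tab <- table(factor(lt$attribute, levels = c("benefit", "cost", "interval")))
  cat(sprintf("  attributes: %d benefit, %d cost, %d interval\n",
              tab[["benefit"]], tab[["cost"]], tab[["interval"]]))
  invisible(x)
}
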