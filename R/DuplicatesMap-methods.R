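#' @include AllClasses.R
NULL

#' @describeIn DuplicatesMap-class Number of stored pairs.
#' @param x A `DuplicatesMap`.
#' @export
setMethod("length", "DuplicatesMap", function(x) length(x@keys))

#' @rdname mapKeys
#' @export
setMethod("mapKeys", "DuplicatesMap", function(x) x@keys)

#' @rdname mapValues
#' @export
setMethod("mapValues", "DuplicatesMap", function(x) x@values)

#' @rdname mapGet
#' @export
setMethod("mapGet", "DuplicatesMap", function(x, key) {
  x@values[x@keys == key]
})

#' @rdname mapGetOne
#' @export
setMethod("mapGetOne", "DuplicatesMap", function(x, key, default = NULL) {
  hits <- which(x@keys == key)
  if (length(hits) == 0) return(default)
  if (length(hits) > 1)
    stop("key '", key, "' is duplicated (", length(hits),
         " occurrences); use mapGet() to retrieve all values")
  x@values[[hits]]
})

#' @rdname mapAppend
#' @export
setMethod("mapAppend", "DuplicatesMap", function(x, key, value) {
  x@keys <- c(x@keys, key)
  x@values <- c(x@values, list(value))
  x
})

#' @rdname mapSet
#' @export
setMethod("mapSet", "DuplicatesMap", function(x, key, value) {
  hits <- which(x@keys == key)
  if (length(hits) == 0) return(mapAppend(x, key, value))
  first <- hits[1]
  x@values[[first]] <- value
  drop <- hits[-1]
  if (length(drop)) {
    x@keys <- x@keys[-drop]
    x@values <- x@values[-drop]
  }
  x
})

#' @rdname mapHas
#' @export
setMethod("mapHas", "DuplicatesMap", function(x, key) key %in% x@keys)

#' @rdname mapDrop
#' @export
setMethod("mapDrop", "DuplicatesMap", function(x, key) {
  keep <- x@keys != key
  x@keys <- x@keys[keep]
  x@values <- x@values[keep]
  x
})

#' @describeIn DuplicatesMap-class Convert to a named list (names may repeat).
#' @param ... Ignored.
#' @export
setMethod("as.list", "DuplicatesMap", function(x, ...) {
  out <- x@values
  names(out) <- x@keys
  out
})

setMethod("show", "DuplicatesMap", function(object) {
  n <- length(object@keys)
  cat("DuplicatesMap with ", n, " pair", if (n != 1) "s", sep = "")
  dup <- sum(duplicated(object@keys))
  if (dup) cat(" (", dup, " duplicated key", if (dup != 1) "s", ")", sep = "")
  cat("\n")
  if (n) {
    shown <- utils::head(seq_len(n), 8)
    for (i in shown) {
      v <- object@values[[i]]
      vtxt <- if (is.character(v) && length(v) == 1) v else paste0("<", class(v)[1], ">")
      if (nchar(vtxt) > 50) vtxt <- paste0(substr(vtxt, 1, 47), "...")
      cat("  ", object@keys[i], ": ", vtxt, "\n", sep = "")
    }
    if (n > 8) cat("  ... and ", n - 8, " more\n", sep = "")
  }
})

# Internal: two maps hold the same pairs in the same order.
dmIdentical <- function(a, b) {
  identical(a@keys, b@keys) && identical(a@values, b@values)
}

# Internal: dictionary-style equality -- same key multiset and, per key, the
# same ordered value list. Order of distinct keys is not compared.
dmEquivalent <- function(a, b) {
  ka <- unique(a@keys); kb <- unique(b@keys)
  if (!setequal(ka, kb)) return(FALSE)
  for (k in ka) if (!identical(mapGet(a, k), mapGet(b, k))) return(FALSE)
  TRUE
}
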