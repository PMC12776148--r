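#' @include column-registry.R
NULL

#' Normalize a column name for matching
#'
#' Lowercases, strips surrounding whitespace and collapses runs of spaces,
#' underscores and hyphens to a single underscore, so `"Ret Time"`,
#' `"ret_time"` and `"ret-time"` normalize identically. Deterministic and
#' idempotent.
#'
#' @param raw Raw column name(s).
#' @return Normalized name(s).
#' @examples
#' normalizeColumnName("Ret Time") == normalizeColumnName("ret_time")
#' @export
normalizeColumnName <- function(raw) {
  x <- tolower(trimws(raw))
  gsub("[ _-]+", "_", x)
}

finderMatches <- function(finder, normalized) {
  any(vapply(finder@patterns, function(p)
    grepl(paste0("^(?:", p, ")$"), normalized, perl = TRUE), logical(1)))
}

#' Match a raw column name against the finder registry
#'
#' Pure function: returns every canonical name whose rules accept the
#' normalized raw name. Zero, one or several matches are all legitimate
#' outcomes -- a multi-match is the signature of a column pulling double
#' duty, which the validator reports rather than silently resolving.
#'
#' @param raw Raw column name.
#' @param registry Finder registry; see [defaultColumnRegistry()].
#' @return Character vector of canonical names (possibly empty).
#' @examples
#' matchColumnName("ret_time")
#' matchColumnName("m/z")
#' @export
matchColumnName <- function(raw, registry = defaultColumnRegistry()) {
  normalized <- normalizeColumnName(raw)
  hits <- vapply(registry, finderMatches, logical(1), normalized = normalized)
  names(registry)[hits]
}

#' Match every header entry of a table
#'
#' One outcome per header entry: the raw name, the set of matched canonical
#' names, and whether the raw spelling already *is* one of the matched
#' canonicals. Exact-canonical names produce a match but are not rename
#' candidates; any other spelling -- including case or separator variants --
#' is, since the depositor should rename it to the canonical form.
#'
#' @param header Character vector of column names.
#' @inheritParams matchColumnName
#' @return List of outcomes, each
#'   `list(raw, matches, isCanonical, renameCandidate)`.
#' @export
findStandardColumns <- function(header, registry = defaultColumnRegistry()) {
  lapply(header, function(raw) {
    matches <- matchColumnName(raw, registry)
    isCanonical <- raw %in% matches
    list(raw = raw, matches = matches, isCanonical = isCanonical,
         renameCandidate = length(matches) > 0 && !isCanonical)
  })
}

#' Validate the values of a standard column
#'
#' Applies the finder's value rule to each value; empty values are never
#' "bad" here (nullness is a separate check's concern). A canonical without
#' a value rule validates vacuously.
#'
#' @param canonical Canonical column name present in the registry.
#' @param values Character vector of cell values.
#' @inheritParams matchColumnName
#' @return Integer vector of 1-based indices of non-empty values rejected by
#'   the rule.
#' @examples
#' validateColumnValues("kegg_id", c("C00031", "banana"))
#' @export
validateColumnValues <- function(canonical, values,
                                 registry = defaultColumnRegistry()) {
  finder <- registry[[canonical]]
  if (is.null(finder)) stop("unknown canonical column name: ", canonical)
  if (length(finder@valuePattern) == 0) return(integer(0))
  vals <- as.character(values)
  nonEmpty <- !is.na(vals) & nzchar(trimws(vals))
  bad <- nonEmpty & !grepl(finder@valuePattern[1], vals, perl = TRUE)
  which(bad)
}
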