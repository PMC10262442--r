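#' Build an empowerment item schema
#'
#' The empowerment instrument has 15 ordinal items in three domains:
#' 7 household decision-making items, 3 freedom-of-movement items and
#' 5 control-over-assets items. Responses are coded with higher numbers
#' indicating greater empowerment; item j takes integer codes
#' `0, 1, ..., n_levels[j] - 1`.
#'
#' @param n_levels integer vector of length 15 giving the number of ordered
#'   response levels per item (each >= 2). Default: three levels per item.
#' @return An object of class `item_schema`: a data.frame with one row per
#'   item (`item`, `domain`, `n_levels`, `max_code`).
#' @export
item_schema <- function(n_levels = rep(3L, 15L)) {
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 15L) {
    stop("an item schema has exactly 15 items (7 decision, 3 movement, 5 assets)")
  }
  if (any(n_levels < 2L)) stop("every item needs at least 2 response levels")
  domains <- c(rep("decision", 7L), rep("movement", 3L), rep("assets", 5L))
  schema <- data.frame(
    item = paste0("item_", seq_len(15L)),
    domain = domains,
    n_levels = n_levels,
    max_code = n_levels - 1L,
    stringsAsFactors = FALSE
  )
  class(schema) <- c("item_schema", "data.frame")
  schema
}

#' @rdname item_schema
#' @param x object to test
#' @export
is_item_schema <- function(x) inherits(x, "item_schema")

# Check a matrix/data.frame of responses (n x 15, integer codes) against a
# schema; stops with the offending item index on violation.
validate_item_responses <- function(responses, schema) {
  stopifnot(is_item_schema(schema))
  responses <- as.matrix(responses)
  if (ncol(responses) != 15L) stop("expected 15 item-response columns")
  if (any(is.na(responses))) stop("item responses must be complete")
  if (any(responses != round(responses))) stop("item responses must be integer codes")
  for (j in seq_len(15L)) {
    bad <- responses[, j] < 0 | responses[, j] > schema$max_code[j]
    if (any(bad)) {
      stop(sprintf("invalid response level for item %d (allowed 0..%d)",
                   j, schema$max_code[j]))
    }
  }
  storage.mode(responses) <- "integer"
  responses
}

domain_columns <- function(schema, domain) which(schema$domain == domain)
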