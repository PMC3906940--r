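#' Read a binary trait table
#'
#' Species-to-state tables code each species as `0` (the ancestral pure
#' freshwater state, F) or `1` (the derived anadromous state, A). The TSV
#' must have columns `species` and `state`.
#'
#' @param path TSV path.
#' @return named integer vector of 0/1 states.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(df)))
    stop("trait table needs columns 'species' and 'state'")
  st <- df$state
  if (!all(st %in% c(0L, 1L))) stop("states must be exactly 0 or 1")
  if (anyDuplicated(df$species)) stop("duplicate species in trait table")
  stats::setNames(as.integer(st), df$species)
}

#' Write a binary trait table
#' @param states named 0/1 vector.
#' @param path output TSV path.
#' @export
write_trait_table <- function(states, path) {
  stopifnot(all(states %in% c(0L, 1L)), !is.null(names(states)))
  utils::write.table(data.frame(species = names(states),
                                state = as.integer(states)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check that every tip of `tree` has a trait entry; returns states ordered
# as tree$tip.label.
match_traits <- function(tree, states) {
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips without trait entry: ", paste(miss, collapse = ", "))
  st <- states[tree$tip.label]
  if (!all(st %in% c(0L, 1L))) stop("states must be 0 or 1")
  st
}

#' Read a sea-level (or other climate) time series
#'
#' CSV with columns `age_ma` (Ma before present, >= 0) and `value`
#' (e.g. metres relative to present sea level).
#'
#' @param path CSV path.
#' @return a `data.frame` of class `"sealevel_series"`.
#' @export
read_sealevel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_ma", "value") %in% names(df)))
    stop("series needs columns 'age_ma' and 'value'")
  sealevel_series(df$age_ma, df$value)
}

#' Construct a sea-level series
#' @param age_ma ages in Ma before present.
#' @param value values (metres).
#' @return a `data.frame` of class `"sealevel_series"`.
#' @export
sealevel_series <- function(age_ma, value) {
  if (length(age_ma) != length(value)) stop("age and value lengths differ")
  if (any(!is.finite(age_ma)) || any(age_ma < 0)) stop("ages must be finite and >= 0")
  if (any(!is.finite(value))) stop("values must be finite")
  structure(data.frame(age_ma = age_ma, value = value),
            class = c("sealevel_series", "data.frame"))
}

#' Write a sea-level series
#' @param series a `"sealevel_series"`.
#' @param path output CSV path.
#' @export
write_sealevel <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
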