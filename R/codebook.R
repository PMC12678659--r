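#' Item codebook for a two-wave binary panel
#'
#' A codebook declares the items measured in a panel, their human-readable
#' names, which of the two node groups each belongs to (depressive symptom or
#' health-risk behaviour), the two wave labels, and the file dialect
#' (\code{"wide"} or \code{"long"}) used when reading/writing panel CSVs.
#'
#' @param item_ids Character vector of unique short item labels, e.g.
#'   \code{"Dep1"}..\code{"Dep12"}, \code{"S"}, \code{"P"}, \code{"F"}, \code{"D"}.
#' @param item_names Character vector of human-readable item names, same
#'   length as \code{item_ids}. Defaults to \code{item_ids}.
#' @param item_group Character vector with entries in
#'   \code{c("depression", "behaviour")}, one per item.
#' @param wave_labels Character vector of length 2 naming the waves.
#' @param format Default file dialect, \code{"wide"} (wave-suffixed columns
#'   \code{".w1"}/\code{".w2"}) or \code{"long"} (a \code{wave} column).
#' @return An object of class \code{"codebook"}.
#' @seealso [default_codebook()], [read_codebook()], [read_panel()]
#' @export
codebook <- function(item_ids, item_names = item_ids, item_group,
                     wave_labels = c("w1", "w2"), format = c("wide", "long")) {
  format <- match.arg(format)
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids))
    stop("codebook: item_ids must be unique")
  if (length(item_names) != length(item_ids))
    stop("codebook: item_names must match item_ids in length")
  item_group <- as.character(item_group)
  if (length(item_group) != length(item_ids))
    stop("codebook: every item needs a group")
  if (!all(item_group %in% c("depression", "behaviour")))
    stop("codebook: item_group entries must be 'depression' or 'behaviour'")
  if (length(wave_labels) != 2L)
    stop("codebook: exactly two waves are supported")
  structure(
    list(item_ids = item_ids,
         item_names = as.character(item_names),
         item_group = stats::setNames(item_group, item_ids),
         wave_labels = as.character(wave_labels),
         format = format),
    class = "codebook")
}

#' Default 16-item codebook (12 depressive symptoms + 4 behaviours)
#'
#' The standard node set used throughout the package: the 12 binary EURO-D
#' depressive-symptom indicators (Dep1--Dep12) and four health-risk
#' behaviours: current smoking (S), physical inactivity (P), less-than-daily
#' fruit/vegetable consumption (F) and heavy episodic drinking (D).
#'
#' @param format File dialect, see [codebook()].
#' @return A \code{"codebook"} object with 16 items.
#' @export
default_codebook <- function(format = c("wide", "long")) {
  format <- match.arg(format)
  dep_names <- c("Depression", "Pessimism", "Suicidality", "Guilt", "Sleep",
                 "Interest", "Irritability", "Appetite", "Fatigue",
                 "Concentration", "Enjoyment", "Tearfulness")
  codebook(
    item_ids = c(paste0("Dep", 1:12), "S", "P", "F", "D"),
    item_names = c(dep_names, "Present smoker", "Physical inactivity",
                   "Low fruit/veg consumption", "Heavy episodic drinking"),
    item_group = c(rep("depression", 12), rep("behaviour", 4)),
    wave_labels = c("w1", "w2"),
    format = format)
}

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook:", length(x$item_ids), "items, waves",
      paste(x$wave_labels, collapse = "/"),
      sprintf("(%s format)\n", x$format))
  grp <- table(x$item_group)
  cat("  ", paste(sprintf("%s: %d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a codebook as JSON
#'
#' @param path Path to a JSON file.
#' @return \code{read_codebook} returns a \code{"codebook"};
#'   \code{write_codebook} returns \code{path} invisibly.
#' @export
read_codebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("item_ids", "item_group", "wave_labels")
  if (!all(need %in% names(x)))
    stop("codebook JSON missing fields: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  grp <- x$item_group
  if (!is.null(names(grp))) grp <- grp[x$item_ids]
  codebook(item_ids = x$item_ids,
           item_names = if (is.null(x$item_names)) x$item_ids else x$item_names,
           item_group = unname(unlist(grp)),
           wave_labels = x$wave_labels,
           format = if (is.null(x$format)) "wide" else x$format)
}

#' @rdname read_codebook
#' @param cb A \code{"codebook"} object.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  jsonlite::write_json(
    list(item_ids = cb$item_ids, item_names = cb$item_names,
         item_group = as.list(cb$item_group),
         wave_labels = cb$wave_labels, format = cb$format),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# node-group partition as a named vector, used by bridge metrics
codebook_partition <- function(cb) cb$item_group
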