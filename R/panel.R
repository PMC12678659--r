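#' Two-wave binary panel container
#'
#' Holds a subjects x items x waves array of 0/1 indicators (NA allowed before
#' inclusion filtering), per-subject group labels (diabetes / no_diabetes) and
#' the item codebook.
#'
#' @param values Numeric array of dimension \code{n x p x 2} with entries in
#'   \{0, 1, NA\}.
#' @param subject_ids Character or integer vector of length \code{n}.
#' @param group Character vector of per-subject labels, values in
#'   \code{c("diabetes", "no_diabetes")} or NA.
#' @param codebook A [codebook()] describing the \code{p} items and 2 waves.
#' @return An object of class \code{"binary_panel"}.
#' @export
binary_panel <- function(values, subject_ids = NULL, group, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  p <- length(codebook$item_ids)
  storage.mode(values) <- "double"
  if (length(dim(values)) != 3L)
    stop("binary_panel: values must be a 3-d array (subjects x items x waves)")
  if (dim(values)[2] != p || dim(values)[3] != 2L)
    stop("binary_panel: array dimensions inconsistent with codebook (need n x ",
         p, " x 2)")
  n <- dim(values)[1]
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  if (length(subject_ids) != n)
    stop("binary_panel: subject_ids length must equal number of subjects")
  bad <- !(values %in% c(0, 1)) & !is.na(values)
  if (any(bad))
    stop("binary_panel: entries must be 0, 1 or missing; found ",
         paste(utils::head(unique(values[bad]), 3), collapse = ", "))
  group <- as.character(group)
  if (length(group) != n)
    stop("binary_panel: group must have one label per subject")
  known <- group %in% c("diabetes", "no_diabetes") | is.na(group)
  if (!all(known))
    stop("binary_panel: unknown group label(s): ",
         paste(unique(group[!known]), collapse = ", "))
  dimnames(values) <- list(as.character(subject_ids), codebook$item_ids,
                           codebook$wave_labels)
  structure(list(values = values,
                 subject_ids = as.character(subject_ids),
                 group = group,
                 codebook = codebook),
            class = "binary_panel")
}

#' @export
print.binary_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Binary panel: %d subjects x %d items x %d waves\n",
              d[1], d[2], d[3]))
  tab <- table(factor(x$group, levels = c("diabetes", "no_diabetes")),
               useNA = "ifany")
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.binary_panel <- function(x) dim(x$values)

#' Number of subjects in a panel
#' @param panel A \code{"binary_panel"}.
#' @return Integer subject count.
#' @export
n_subjects <- function(panel) dim(panel$values)[1]

#' Extract one wave of a panel as an n x p matrix
#'
#' @param panel A \code{"binary_panel"}.
#' @param wave Wave index (1 or 2) or wave label.
#' @return Numeric \code{n x p} matrix of 0/1 (and NA if present).
#' @export
panel_wave <- function(panel, wave = 1) {
  stopifnot(inherits(panel, "binary_panel"))
  if (is.character(wave)) wave <- match(wave, panel$codebook$wave_labels)
  if (is.na(wave) || !wave %in% 1:2) stop("panel_wave: wave must be 1 or 2")
  panel$values[, , wave, drop = FALSE][, , 1]
}

#' Subset a panel by subject index
#'
#' @param panel A \code{"binary_panel"}.
#' @param idx Integer or logical subject index.
#' @return A \code{"binary_panel"} restricted to the selected subjects.
#' @export
panel_subset <- function(panel, idx) {
  stopifnot(inherits(panel, "binary_panel"))
  binary_panel(panel$values[idx, , , drop = FALSE],
               subject_ids = panel$subject_ids[idx],
               group = panel$group[idx],
               codebook = panel$codebook)
}

#' Read a two-wave binary panel from CSV
#'
#' The codebook declares the dialect. Wide format has one row per subject and
#' wave-suffixed item columns (\code{Dep1.w1}, \code{Dep1.w2}, ...); long
#' format has one row per subject-wave with a \code{wave} column (values 1/2)
#' and unsuffixed item columns. Both need \code{subject_id} and \code{group}
#' columns. Cells must be 0, 1, empty or the literal \code{NA}; anything else
#' is a parse error naming the offending line.
#'
#' @param path CSV file path.
#' @param codebook_path Path to a codebook JSON, or a \code{"codebook"} object.
#' @return A \code{"binary_panel"}.
#' @seealso [write_panel()]
#' @export
read_panel <- function(path, codebook_path) {
  cb <- if (inherits(codebook_path, "codebook")) codebook_path
        else read_codebook(codebook_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("read_panel: file must have 'subject_id' and 'group' columns")
  p <- length(cb$item_ids)

  parse_items <- function(cols, rows_offset) {
    m <- matrix(NA_real_, nrow = nrow(cols), ncol = ncol(cols))
    for (j in seq_len(ncol(cols))) {
      v <- trimws(cols[[j]])
      ok0 <- v == "0"; ok1 <- v == "1"; okna <- v == "" | v == "NA"
      bad <- which(!(ok0 | ok1 | okna))
      if (length(bad))
        stop(sprintf(
          "read_panel: invalid value '%s' in column '%s' at line %d (must be 0, 1 or NA)",
          v[bad[1]], names(cols)[j], bad[1] + rows_offset + 1L))
      m[ok1, j] <- 1; m[ok0, j] <- 0
    }
    colnames(m) <- names(cols)
    m
  }

  if (cb$format == "wide") {
    want <- as.vector(outer(cb$item_ids, cb$wave_labels, paste, sep = "."))
    missing_cols <- setdiff(want, names(df))
    if (length(missing_cols))
      stop("read_panel: schema error, missing item columns: ",
           paste(utils::head(missing_cols, 4), collapse = ", "))
    extra <- setdiff(names(df), c("subject_id", "group", want))
    if (length(extra))
      stop("read_panel: schema error, unknown item column(s): ",
           paste(utils::head(extra, 4), collapse = ", "))
    n <- nrow(df)
    vals <- array(NA_real_, dim = c(n, p, 2))
    for (w in 1:2) {
      cols <- paste(cb$item_ids, cb$wave_labels[w], sep = ".")
      vals[, , w] <- parse_items(df[cols], 0L)
    }
    subj <- df$subject_id
    grp <- df$group
  } else {
    if (!"wave" %in% names(df))
      stop("read_panel: long format requires a 'wave' column")
    missing_cols <- setdiff(cb$item_ids, names(df))
    if (length(missing_cols))
      stop("read_panel: schema error, missing item columns: ",
           paste(utils::head(missing_cols, 4), collapse = ", "))
    extra <- setdiff(names(df), c("subject_id", "group", "wave", cb$item_ids))
    if (length(extra))
      stop("read_panel: schema error, unknown item column(s): ",
           paste(utils::head(extra, 4), collapse = ", "))
    if (!all(df$wave %in% c("1", "2")))
      stop("read_panel: wave column must contain 1 or 2")
    subj <- unique(df$subject_id)
    n <- length(subj)
    vals <- array(NA_real_, dim = c(n, p, 2))
    m <- parse_items(df[cb$item_ids], 0L)
    ridx <- match(df$subject_id, subj)
    widx <- as.integer(df$wave)
    for (k in seq_len(nrow(df)))
      vals[ridx[k], , widx[k]] <- m[k, ]
    grp <- df$group[match(subj, df$subject_id)]
  }
  grp[grp == "" | grp == "NA"] <- NA_character_
  binary_panel(vals, subject_ids = subj, group = grp, codebook = cb)
}

#' Write a panel to CSV in the codebook's dialect
#'
#' @param panel A \code{"binary_panel"}.
#' @param path Output CSV path.
#' @param format Override the codebook's dialect.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path, format = panel$codebook$format) {
  stopifnot(inherits(panel, "binary_panel"))
  cb <- panel$codebook
  fmt_val <- function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE))
  if (format == "wide") {
    out <- data.frame(subject_id = panel$subject_ids,
                      group = ifelse(is.na(panel$group), "NA", panel$group),
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (w in 1:2)
      for (j in seq_along(cb$item_ids))
        out[[paste(cb$item_ids[j], cb$wave_labels[w], sep = ".")]] <-
          fmt_val(panel$values[, j, w])
  } else {
    n <- n_subjects(panel)
    out <- data.frame(
      subject_id = rep(panel$subject_ids, times = 2),
      group = rep(ifelse(is.na(panel$group), "NA", panel$group), times = 2),
      wave = rep(1:2, each = n),
      stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(cb$item_ids))
      out[[cb$item_ids[j]]] <-
        fmt_val(c(panel$values[, j, 1], panel$values[, j, 2]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Apply the participant-selection (inclusion) filter
#'
#' Subjects are retained only with a non-missing group label and complete data
#' on all items at both waves. Exclusion reasons follow the selection
#' flowchart order, and each subject is logged under the first applicable
#' reason only: \code{missing_group} (diabetes question unanswered), then
#' \code{missing_item} (one or more items missing within an otherwise observed
#' wave), then \code{single_wave} (an entire wave absent).
#'
#' @param panel A \code{"binary_panel"}, possibly with missing entries.
#' @return A list with \code{panel} (complete-case panel) and
#'   \code{exclusion_log}: counts per reason plus retained/input totals.
#' @export
apply_inclusion_filter <- function(panel) {
  stopifnot(inherits(panel, "binary_panel"))
  n <- n_subjects(panel)
  miss1 <- rowSums(is.na(panel$values[, , 1, drop = FALSE]))
  miss2 <- rowSums(is.na(panel$values[, , 2, drop = FALSE]))
  p <- dim(panel$values)[2]
  wave_absent <- (miss1 == p) | (miss2 == p)
  wave_partial <- (miss1 > 0 & miss1 < p) | (miss2 > 0 & miss2 < p)

  reason <- rep(NA_character_, n)
  reason[wave_absent] <- "single_wave"
  reason[wave_partial] <- "missing_item"   # takes precedence over single_wave
  reason[is.na(panel$group)] <- "missing_group"

  keep <- is.na(reason)
  if (!any(keep))
    stop("apply_inclusion_filter: no subjects remain after filtering")
  log <- list(
    input = n,
    excluded = list(
      missing_group = sum(reason == "missing_group", na.rm = TRUE),
      missing_item = sum(reason == "missing_item", na.rm = TRUE),
      single_wave = sum(reason == "single_wave", na.rm = TRUE)),
    retained = sum(keep))
  list(panel = panel_subset(panel, keep), exclusion_log = log)
}

#' Split a panel into its diabetes and no-diabetes groups
#'
#' @param panel A \code{"binary_panel"} with non-missing group labels.
#' @return Named list with \code{diabetes} and \code{no_diabetes} panels;
#'   sizes always sum to the input size. Warns if a group is empty.
#' @export
split_by_group <- function(panel) {
  stopifnot(inherits(panel, "binary_panel"))
  if (anyNA(panel$group))
    stop("split_by_group: missing group labels; run apply_inclusion_filter first")
  idx_d <- panel$group == "diabetes"
  if (!any(idx_d) || all(idx_d))
    warning("split_by_group: one group is empty")
  list(diabetes = panel_subset(panel, idx_d),
       no_diabetes = panel_subset(panel, !idx_d))
}

#' Recode raw survey answers into the binary behaviour indicators
#'
#' Maps raw interview responses to the four behaviour nodes: S = 1 iff
#' currently smoking; F = 1 iff eating fruit/vegetables less than daily;
#' D = 1 iff six or more drinks on at least one occasion in the last three
#' months (life-long non-drinkers score 0); P = 1 iff never vigorous nor
#' moderate physical activity.
#'
#' @param record Named list with fields \code{smoke_now} ("yes"/"no"),
#'   \code{smoke_ever} ("yes"/"no"), \code{fruitveg} ("daily"/"less_than_daily"),
#'   \code{drinks_6plus} ("never"/"at_least_once"), \code{drinks_alcohol}
#'   ("yes"/"never"), \code{activity} ("never_vigorous_nor_moderate"/"other").
#'   A missing (NULL/NA) answer yields NA for the affected indicator.
#' @return Named numeric vector \code{c(S=, P=, F=, D=)} with entries in
#'   \{0, 1, NA\}.
#' @export
recode_behaviours <- function(record) {
  pick <- function(field) {
    v <- record[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NA_character_
    else as.character(v)
  }
  chk <- function(value, allowed, field) {
    if (!is.na(value) && !value %in% allowed)
      stop(sprintf("recode_behaviours: invalid answer '%s' for %s", value, field))
    value
  }
  smoke_now <- chk(pick("smoke_now"), c("yes", "no"), "smoke_now")
  smoke_ever <- chk(pick("smoke_ever"), c("yes", "no"), "smoke_ever")
  fruitveg <- chk(pick("fruitveg"), c("daily", "less_than_daily"), "fruitveg")
  d6 <- chk(pick("drinks_6plus"), c("never", "at_least_once"), "drinks_6plus")
  drinks <- chk(pick("drinks_alcohol"), c("yes", "never"), "drinks_alcohol")
  act <- chk(pick("activity"), c("never_vigorous_nor_moderate", "other"),
             "activity")

  S <- if (!is.na(smoke_now)) {
    as.numeric(smoke_now == "yes")
  } else if (!is.na(smoke_ever) && smoke_ever == "no") 0 else NA_real_
  P <- if (is.na(act)) NA_real_ else as.numeric(act == "never_vigorous_nor_moderate")
  F_ <- if (is.na(fruitveg)) NA_real_ else as.numeric(fruitveg == "less_than_daily")
  D <- if (!is.na(drinks) && drinks == "never") {
    0  # never-drinkers coded 0 regardless of the episodic question
  } else if (!is.na(d6)) as.numeric(d6 == "at_least_once") else NA_real_
  c(S = S, P = P, F = F_, D = D)
}
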