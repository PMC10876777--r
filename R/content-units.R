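#' Detect which content units a sample mentions
#'
#' A content unit is detected when any of its variant forms matches the
#' sample's lower-cased lemma sequence; multiword forms must match a run of
#' consecutive lemmas. Matching is exact (dictionary-based) — no fuzzy or
#' edit-distance matching, which would change counts silently. Each unit is
#' counted at most once per sample regardless of how many times it is
#' mentioned, and morphological variants grouped under the same unit (e.g.
#' "girl" and "daughter") still count as a single unit.
#'
#' @param sample An annotated [transcript_sample()] (lemmas available).
#' @param dict A [cu_dictionary()].
#' @return Character vector of detected unit ids (a set; order follows the
#'   dictionary).
#' @export
detect_content_units <- function(sample, dict) {
  tok <- sample$tokens
  if (nrow(tok) == 0L) return(character())
  if (anyNA(tok$lemma)) {
    stop("unannotated sample: run annotate_sample() first", call. = FALSE)
  }
  lemmas <- tolower(tok$lemma)
  haystack <- paste0(" ", paste(lemmas, collapse = " "), " ")
  hit <- vapply(dict$units, function(forms) {
    any(vapply(forms, function(f) {
      grepl(paste0(" ", f, " "), haystack, fixed = TRUE)
    }, logical(1L)))
  }, logical(1L))
  names(dict$units)[hit]
}

#' Total number of content units in a sample
#'
#' @inheritParams detect_content_units
#' @return Non-negative integer, at most the number of dictionary units.
#' @export
total_content_units <- function(sample, dict) {
  length(detect_content_units(sample, dict))
}

#' Was the theme unit mentioned?
#'
#' The theme unit (for the picnic scene, "picnic") expresses the gist of the
#' whole picture; failing to mention it while naming its components is the
#' signature of simultanagnosia.
#'
#' @inheritParams detect_content_units
#' @return `1L` if the theme unit was detected, else `0L`.
#' @export
theme_mentioned <- function(sample, dict) {
  as.integer(dict$theme_unit %in% detect_content_units(sample, dict))
}

#' Build a binary mention matrix for a cohort
#'
#' One row per participant, one column per dictionary unit, cells 0/1
#' indicating whether the participant mentioned the unit at least once.
#' Column proportions are the per-unit empirical mention probabilities used
#' by the group screen.
#'
#' @param samples Non-empty list of annotated [transcript_sample()] objects,
#'   all from the same task.
#' @param dict A [cu_dictionary()].
#' @return An object of class `mention_matrix`: a list with `mentions` (binary
#'   integer matrix, rownames = participant ids, colnames = unit ids) and
#'   `group` (character vector aligned to rows).
#' @export
mention_matrix <- function(samples, dict) {
  if (length(samples) == 0L) stop("empty cohort", call. = FALSE)
  tasks <- vapply(samples, `[[`, character(1L), "task")
  if (length(unique(tasks)) > 1L) {
    stop("mixed tasks in cohort: ", paste(unique(tasks), collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(samples, `[[`, character(1L), "participant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id in cohort: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  unit_ids <- names(dict$units)
  m <- matrix(0L, nrow = length(samples), ncol = length(unit_ids),
              dimnames = list(ids, unit_ids))
  for (i in seq_along(samples)) {
    m[i, detect_content_units(samples[[i]], dict)] <- 1L
  }
  structure(
    list(mentions = m,
         group = vapply(samples, `[[`, character(1L), "group")),
    class = "mention_matrix"
  )
}

#' @export
print.mention_matrix <- function(x, ...) {
  cat(sprintf("<mention_matrix> %d participants x %d units (%s)\n",
              nrow(x$mentions), ncol(x$mentions),
              paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a mention matrix to CSV
#'
#' @param mm A [mention_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mention_matrix <- function(mm, path) {
  out <- data.frame(participant_id = rownames(mm$mentions),
                    group = mm$group, mm$mentions, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
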