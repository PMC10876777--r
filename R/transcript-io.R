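#' Construct a timed transcript sample
#'
#' A transcript sample is one participant x task utterance sequence: an
#' ordered sequence of spoken words with onset/offset times in seconds, plus
#' the participant's group label. Linguistic annotation (lemma, universal POS,
#' dependency relation) and syllable counts are optional until filled by
#' [annotate_sample()] and the feature extractors.
#'
#' @param participant_id Non-empty string, unique within a cohort x task.
#' @param group Group label, `"PCA"` (patients) or `"CN"` (controls).
#' @param task Task label, `"picture"` or `"job"`.
#' @param tokens Data frame with columns `text`, `start`, `end` and optionally
#'   `lemma`, `upos`, `deprel`, `syllables`. Times are decimal seconds;
#'   `start` must be non-decreasing and every `end >= start`.
#' @return An object of class `transcript_sample`.
#' @export
transcript_sample <- function(participant_id, group, task, tokens) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            nzchar(participant_id))
  group <- match.arg(group, c("PCA", "CN"))
  task <- match.arg(task, c("picture", "job"))
  tokens <- as_token_table(tokens)
  x <- structure(
    list(participant_id = participant_id, group = group, task = task,
         tokens = tokens),
    class = "transcript_sample"
  )
  validate_transcript_sample(x)
}

token_columns <- c("text", "start", "end", "lemma", "upos", "deprel", "syllables")

as_token_table <- function(tokens) {
  tokens <- tibble::as_tibble(tokens)
  if (nrow(tokens) == 0L && !all(c("text", "start", "end") %in% names(tokens))) {
    tokens <- tibble::tibble(text = character(), start = numeric(),
                             end = numeric())
  }
  for (col in c("lemma", "upos", "deprel")) {
    if (is.null(tokens[[col]])) tokens[[col]] <- rep(NA_character_, nrow(tokens))
  }
  if (is.null(tokens[["syllables"]])) {
    tokens$syllables <- rep(NA_integer_, nrow(tokens))
  }
  tokens$start <- parse_seconds(tokens$start)
  tokens$end <- parse_seconds(tokens$end)
  tokens[token_columns]
}

# Accepts plain numbers or ASR-style duration strings such as "1.300s".
parse_seconds <- function(x) {
  if (is.character(x)) x <- sub("s$", "", trimws(x))
  as.numeric(x)
}

validate_transcript_sample <- function(x) {
  tok <- x$tokens
  if (nrow(tok) == 0L) return(x)
  txt <- trimws(tok$text)
  if (any(!nzchar(txt) | is.na(txt))) {
    stop("transcript '", x$participant_id, "': empty word text at token ",
         which(!nzchar(txt) | is.na(txt))[1L], call. = FALSE)
  }
  if (any(is.na(tok$start)) || any(is.na(tok$end))) {
    stop("transcript '", x$participant_id, "': unparseable time at token ",
         which(is.na(tok$start) | is.na(tok$end))[1L], call. = FALSE)
  }
  if (any(tok$start < 0)) {
    stop("transcript '", x$participant_id, "': negative start time at token ",
         which(tok$start < 0)[1L], call. = FALSE)
  }
  bad <- which(tok$end < tok$start)
  if (length(bad)) {
    stop("transcript '", x$participant_id, "': end < start at token ", bad[1L],
         " ('", tok$text[bad[1L]], "')", call. = FALSE)
  }
  if (is.unsorted(tok$start)) {
    stop("transcript '", x$participant_id,
         "': token start times must be non-decreasing", call. = FALSE)
  }
  x
}

#' @export
print.transcript_sample <- function(x, ...) {
  cat(sprintf("<transcript_sample> %s  group=%s  task=%s  %d tokens\n",
              x$participant_id, x$group, x$task, nrow(x$tokens)))
  if (nrow(x$tokens)) {
    cat(sprintf("  span %.2f-%.2f s; annotated: %s\n",
                min(x$tokens$start), max(x$tokens$end),
                ifelse(is_annotated(x), "yes", "no")))
  }
  invisible(x)
}

is_annotated <- function(sample) {
  nrow(sample$tokens) > 0L &&
    !anyNA(sample$tokens$lemma) && !anyNA(sample$tokens$upos) &&
    !anyNA(sample$tokens$deprel)
}

#' Read a word-timestamped transcript from JSON
#'
#' The expected schema is the output convention of word-level ASR timestamp
#' APIs: `{"participant_id": str, "group": "PCA"|"CN", "task":
#' "picture"|"job", "words": [{"word": str, "start": num, "end": num,
#' "lemma"?: str, "upos"?: str, "deprel"?: str}]}`. Times may be plain
#' seconds or `"s"`-suffixed strings (`"1.300s"`). Arguments override the
#' corresponding fields in the file.
#'
#' @param path Path to a JSON transcript file.
#' @param participant_id,group,task Optional overrides for the file's fields.
#' @return A [transcript_sample()].
#' @export
read_timed_transcript <- function(path, participant_id = NULL, group = NULL,
                                  task = NULL) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop("malformed transcript JSON in '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  words <- obj$words
  if (is.null(words) || length(words) == 0L) {
    tokens <- tibble::tibble(text = character(), start = numeric(),
                             end = numeric())
  } else {
    words <- tibble::as_tibble(words)
    if (!all(c("word", "start", "end") %in% names(words))) {
      stop("transcript '", path,
           "': each word record needs fields word, start, end", call. = FALSE)
    }
    tokens <- tibble::tibble(
      text = as.character(words$word),
      start = parse_seconds(words$start),
      end = parse_seconds(words$end)
    )
    for (col in c("lemma", "upos", "deprel")) {
      if (!is.null(words[[col]])) tokens[[col]] <- as.character(words[[col]])
    }
  }
  transcript_sample(
    participant_id = participant_id %||% obj$participant_id,
    group = group %||% obj$group,
    task = task %||% obj$task,
    tokens = tokens
  )
}

#' Write a transcript sample to JSON
#'
#' Inverse of [read_timed_transcript()]: the round trip preserves token order,
#' times, and any annotation fields.
#'
#' @param sample A [transcript_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timed_transcript <- function(sample, path) {
  tok <- sample$tokens
  words <- lapply(seq_len(nrow(tok)), function(i) {
    w <- list(word = tok$text[i], start = tok$start[i], end = tok$end[i])
    for (col in c("lemma", "upos", "deprel")) {
      if (!is.na(tok[[col]][i])) w[[col]] <- tok[[col]][i]
    }
    w
  })
  obj <- list(participant_id = sample$participant_id, group = sample$group,
              task = sample$task, words = words)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a directory of timed transcripts
#'
#' @param dir Directory containing `*.json` transcript files.
#' @return A list of [transcript_sample()] objects, in file-name order.
#' @export
read_transcript_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(paths)) stop("no .json transcripts found in '", dir, "'",
                           call. = FALSE)
  lapply(paths, read_timed_transcript)
}

#' Construct a word-frequency lexicon
#'
#' A lexicon maps lower-cased words to raw occurrence counts in a spoken
#' reference corpus (the convention of the Switchboard telephone-speech
#' counts), together with the corpus total. Lookups are case-insensitive.
#' Counts may cover content words only, so the corpus total need not equal
#' the sum of counts.
#'
#' @param counts Named numeric vector of positive counts; names are words.
#' @param corpus_total Positive total word count of the reference corpus.
#' @return An object of class `frequency_lexicon`.
#' @export
frequency_lexicon <- function(counts, corpus_total) {
  stopifnot(length(counts) > 0L, !is.null(names(counts)))
  if (any(is.na(counts)) || any(counts < 1)) {
    bad <- names(counts)[which(is.na(counts) | counts < 1)[1L]]
    stop("lexicon counts must be positive; offending word: '", bad, "'",
         call. = FALSE)
  }
  if (!is.numeric(corpus_total) || length(corpus_total) != 1L ||
      is.na(corpus_total) || corpus_total <= 0) {
    stop("corpus_total must be a positive number", call. = FALSE)
  }
  key <- tolower(names(counts))
  merged <- tapply(as.numeric(counts), key, sum)
  counts <- as.numeric(merged)
  names(counts) <- names(merged)
  structure(list(counts = counts, corpus_total = as.numeric(corpus_total)),
            class = "frequency_lexicon")
}

#' @export
print.frequency_lexicon <- function(x, ...) {
  cat(sprintf("<frequency_lexicon> %d words, corpus total %s\n",
              length(x$counts), format(x$corpus_total, big.mark = ",")))
  invisible(x)
}

#' Read a word-frequency lexicon from TSV
#'
#' Expected format: a first comment line `# corpus_total=<int>`, then a header
#' `word<TAB>count` and one row per word. Words are case-folded and duplicate
#' rows are summed.
#'
#' @param path Path to the TSV file.
#' @return A [frequency_lexicon()].
#' @export
read_frequency_lexicon <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*corpus_total\\s*=\\s*([0-9]+)", first))[[1L]]
  if (length(m) < 2L) {
    stop("lexicon '", path,
         "': missing '# corpus_total=<int>' on the first line", call. = FALSE)
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("word", "count") %in% names(tab))) {
    stop("lexicon '", path, "': expected header word<TAB>count", call. = FALSE)
  }
  counts <- as.numeric(tab$count)
  names(counts) <- as.character(tab$word)
  frequency_lexicon(counts, as.numeric(m[2L]))
}

#' Write a word-frequency lexicon to TSV
#'
#' @param lexicon A [frequency_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_lexicon <- function(lexicon, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# corpus_total=%d", round(lexicon$corpus_total)), con)
  writeLines("word\tcount", con)
  writeLines(sprintf("%s\t%d", names(lexicon$counts),
                     round(lexicon$counts)), con)
  invisible(path)
}

#' Look up raw corpus counts for words
#'
#' @param lexicon A [frequency_lexicon()].
#' @param words Character vector; matching is on lower-cased forms.
#' @return Numeric vector of counts, `NA` for out-of-vocabulary words.
#' @export
lexicon_count <- function(lexicon, words) {
  unname(lexicon$counts[tolower(words)])
}

#' Construct a content-unit dictionary
#'
#' A content-unit dictionary maps unit identifiers to their variant forms:
#' lower-cased lemmas (or space-joined multiword lemma sequences) that all
#' count as mentions of the same correct-information item of the stimulus
#' picture (e.g. "girl" and "daughter" grouped under one unit). One unit is
#' designated the theme unit, whose mention indicates that the speaker grasped
#' the scene's overall gist.
#'
#' @param units Named list: unit id -> character vector of variant forms.
#' @param theme_unit Unit id of the theme unit; must be one of `names(units)`.
#' @return An object of class `cu_dictionary`.
#' @export
cu_dictionary <- function(units, theme_unit) {
  stopifnot(is.list(units), length(units) > 0L, !is.null(names(units)))
  if (anyDuplicated(names(units))) {
    stop("duplicate unit ids: ",
         paste(unique(names(units)[duplicated(names(units))]), collapse = ", "),
         call. = FALSE)
  }
  units <- lapply(units, function(f) tolower(trimws(as.character(f))))
  form_owner <- rep(names(units), lengths(units))
  forms <- unlist(units, use.names = FALSE)
  dup <- which(duplicated(forms))
  if (length(dup)) {
    f <- forms[dup[1L]]
    owners <- unique(form_owner[forms == f])
    stop("variant form '", f, "' listed under more than one unit: ",
         paste(owners, collapse = " and "), call. = FALSE)
  }
  if (!theme_unit %in% names(units)) {
    stop("theme unit '", theme_unit, "' is not among the dictionary units",
         call. = FALSE)
  }
  structure(list(units = units, theme_unit = theme_unit),
            class = "cu_dictionary")
}

#' @export
print.cu_dictionary <- function(x, ...) {
  cat(sprintf("<cu_dictionary> %d units (%d variant forms), theme = '%s'\n",
              length(x$units), sum(lengths(x$units)), x$theme_unit))
  invisible(x)
}

#' Read a content-unit dictionary from JSON
#'
#' Schema: `{"units": {unit_id: [form, ...]}, "theme_unit": unit_id}`;
#' multiword forms are space-joined lemma sequences.
#'
#' @param path Path to the JSON file.
#' @return A [cu_dictionary()].
#' @export
read_cu_dictionary <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$units) || is.null(obj$theme_unit)) {
    stop("content-unit dictionary '", path,
         "' needs fields 'units' and 'theme_unit'", call. = FALSE)
  }
  cu_dictionary(as.list(obj$units), obj$theme_unit)
}

#' Write a content-unit dictionary to JSON
#'
#' @param dict A [cu_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cu_dictionary <- function(dict, path) {
  jsonlite::write_json(list(units = dict$units, theme_unit = dict$theme_unit),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per participant x task, stable column order, full double precision
#' (round-tripping through [read_feature_table()] reproduces the values
#' exactly).
#'
#' @param features Feature table as returned by [extract_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(nrow(features) > 0L)
  key <- paste(features$participant_id, features$task)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, task) row: ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  out <- as.data.frame(features)
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path Path written by [write_feature_table()].
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  char_cols <- c("participant_id", "group", "task")
  for (col in setdiff(names(tab), char_cols)) tab[[col]] <- as.numeric(tab[[col]])
  tibble::as_tibble(tab)
}

#' Read token annotation from a CoNLL-U file
#'
#' Only the FORM, LEMMA, UPOS and DEPREL columns are used; multiword-token
#' ranges, empty nodes and punctuation nodes (UPOS `PUNCT`) are dropped, since
#' ASR word streams carry no punctuation.
#'
#' @param path Path to a CoNLL-U file.
#' @return A tibble with columns `form`, `lemma`, `upos`, `deprel`.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) {
    length(f) >= 8L && grepl("^[0-9]+$", f[1L]) && f[4L] != "PUNCT"
  }, logical(1L))
  fields <- fields[keep]
  tibble::tibble(
    form = vapply(fields, `[[`, character(1L), 2L),
    lemma = vapply(fields, `[[`, character(1L), 3L),
    upos = vapply(fields, `[[`, character(1L), 4L),
    deprel = vapply(fields, `[[`, character(1L), 8L)
  )
}

#' Attach CoNLL-U annotation to a transcript sample
#'
#' Tokens are aligned positionally (after punctuation is dropped by
#' [read_conllu()]); a length mismatch is an error rather than a silent skip.
#'
#' @param sample A [transcript_sample()].
#' @param annotation A tibble from [read_conllu()].
#' @return The annotated sample.
#' @export
apply_conllu_annotation <- function(sample, annotation) {
  n <- nrow(sample$tokens)
  if (nrow(annotation) != n) {
    stop("annotation has ", nrow(annotation), " tokens but transcript '",
         sample$participant_id, "' has ", n,
         "; positional alignment failed", call. = FALSE)
  }
  sample$tokens$lemma <- tolower(annotation$lemma)
  sample$tokens$upos <- annotation$upos
  sample$tokens$deprel <- annotation$deprel
  sample
}

`%||%` <- function(a, b) if (is.null(a)) b else a
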