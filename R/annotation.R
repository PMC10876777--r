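.tagger_registry <- new.env(parent = emptyenv())

#' Register a tagger
#'
#' A tagger is a function taking an ordered character vector of words and
#' returning a data frame with one row per word and columns `lemma`, `upos`
#' (universal POS tag) and `deprel` (universal dependency relation label).
#' Registered taggers are looked up by name in [annotate_sample()], so a
#' full neural tagger (e.g. a Stanza or UDPipe bridge) can be plugged in
#' without changing the pipeline.
#'
#' @param name Tagger name.
#' @param fn Annotation function.
#' @return `name`, invisibly.
#' @export
register_tagger <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .tagger_registry)
  invisible(name)
}

#' Retrieve a registered tagger
#'
#' The deterministic lexicon-based `"fallback"` tagger is always available.
#'
#' @param name Tagger name.
#' @return The annotation function.
#' @export
get_tagger <- function(name = "fallback") {
  if (identical(name, "fallback") &&
      !exists("fallback", envir = .tagger_registry)) {
    register_tagger("fallback", fallback_tagger)
  }
  if (!exists(name, envir = .tagger_registry)) {
    stop("no tagger registered under '", name, "'", call. = FALSE)
  }
  get(name, envir = .tagger_registry)
}

# Closed-class entries for the fallback tagger: word -> lemma, upos, deprel.
# Adpositions carry the dependency relation "case", the operationalization of
# spatial relational words used throughout the package.
closed_class_table <- function() {
  adp <- c("about", "above", "across", "after", "against", "along", "amid",
           "among", "around", "at", "before", "behind", "below", "beneath",
           "beside", "besides", "between", "beyond", "by", "despite", "down",
           "during", "except", "for", "from", "in", "inside", "into", "near",
           "of", "off", "on", "onto", "out", "outside", "over", "past", "per",
           "since", "through", "throughout", "till", "to", "toward",
           "towards", "under", "underneath", "until", "unto", "up", "upon",
           "via", "with", "within", "without")
  det <- c("the", "a", "an", "this", "that", "these", "those", "each",
           "every", "some", "any", "no", "another", "all", "both", "either",
           "neither", "such")
  pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
            "us", "them", "my", "your", "his", "its", "our", "their", "mine",
            "yours", "hers", "ours", "theirs", "myself", "yourself",
            "himself", "herself", "itself", "ourselves", "themselves", "who",
            "whom", "whose", "which", "what", "something", "anything",
            "nothing", "everything", "someone", "anyone", "everyone",
            "somebody", "anybody", "everybody", "nobody", "there")
  aux_forms <- c(am = "be", is = "be", are = "be", was = "be", were = "be",
                 be = "be", been = "be", being = "be", do = "do",
                 does = "do", did = "do", have = "have", has = "have",
                 had = "have", will = "will", would = "will", shall = "shall",
                 should = "shall", can = "can", could = "can", may = "may",
                 might = "may", must = "must")
  cconj <- c("and", "or", "but", "nor", "so", "yet")
  sconj <- c("because", "although", "though", "while", "if", "unless",
             "whereas", "whether", "once")
  intj <- c("um", "uh", "er", "ah", "hmm", "mhm", "oh", "yeah", "okay",
            "yes", "hey", "wow", "huh")
  part <- c("not")
  adv <- c("very", "really", "quite", "too", "also", "just", "here", "now",
           "then", "again", "always", "never", "often", "sometimes", "maybe",
           "perhaps", "well", "only", "even", "still", "already", "soon",
           "together", "away", "back")
  rbind(
    data.frame(word = adp, lemma = adp, upos = "ADP", deprel = "case"),
    data.frame(word = det, lemma = det, upos = "DET", deprel = "det"),
    data.frame(word = pron, lemma = pron, upos = "PRON", deprel = "nsubj"),
    data.frame(word = names(aux_forms), lemma = unname(aux_forms),
               upos = "AUX", deprel = "aux"),
    data.frame(word = cconj, lemma = cconj, upos = "CCONJ", deprel = "cc"),
    data.frame(word = sconj, lemma = sconj, upos = "SCONJ", deprel = "mark"),
    data.frame(word = intj, lemma = intj, upos = "INTJ", deprel = "discourse"),
    data.frame(word = part, lemma = part, upos = "PART", deprel = "advmod"),
    data.frame(word = adv, lemma = adv, upos = "ADV", deprel = "advmod")
  )
}

closed_class <- function() {
  if (is.null(.tagger_registry$.closed_class)) {
    .tagger_registry$.closed_class <- closed_class_table()
  }
  .tagger_registry$.closed_class
}

# Light lemmatizer for open-class words: plural -s, -ing / -ed with doubled
# consonant undoubling. Deliberately conservative; a real tagger supersedes it.
heuristic_lemma <- function(w) {
  if (nchar(w) > 4L && grepl("ing$", w)) {
    stem <- sub("ing$", "", w)
    n <- nchar(stem)
    if (n >= 3L && substr(stem, n, n) == substr(stem, n - 1L, n - 1L)) {
      stem <- substr(stem, 1L, n - 1L)
    }
    return(stem)
  }
  if (nchar(w) > 4L && grepl("ied$", w)) return(sub("ied$", "y", w))
  if (nchar(w) > 3L && grepl("ed$", w)) {
    stem <- sub("d$", "", w)  # keep the e: "hoped" -> "hope"
    return(stem)
  }
  if (nchar(w) > 3L && grepl("ies$", w)) return(sub("ies$", "y", w))
  if (nchar(w) > 3L && grepl("s$", w) &&
      !grepl("(ss|us|is)$", w)) return(sub("s$", "", w))
  w
}

#' Deterministic lexicon-based fallback tagger
#'
#' Annotates words from a ~200-entry closed-class table (adpositions tagged
#' `ADP`/`case`, determiners, pronouns, auxiliaries, conjunctions,
#' interjections) plus suffix heuristics for open-class words (`-ly` adverbs,
#' `-ing`/`-ed` verbs, default noun). It is deterministic across runs and
#' platforms and exists so that tests and offline runs never require a model
#' download; real analyses should plug in a full neural tagger via
#' [register_tagger()].
#'
#' @param words Character vector of surface words.
#' @return A tibble with columns `lemma`, `upos`, `deprel`, one row per word.
#' @export
fallback_tagger <- function(words) {
  cc <- closed_class()
  w <- tolower(trimws(words))
  idx <- match(w, cc$word)
  lemma <- ifelse(is.na(idx), NA_character_, cc$lemma[idx])
  upos <- ifelse(is.na(idx), NA_character_, cc$upos[idx])
  deprel <- ifelse(is.na(idx), NA_character_, cc$deprel[idx])
  open <- which(is.na(idx))
  for (i in open) {
    wi <- w[i]
    if (grepl("^[0-9]+([.,][0-9]+)?$", wi)) {
      lemma[i] <- wi; upos[i] <- "NUM"; deprel[i] <- "nummod"
    } else if (nchar(wi) > 3L && grepl("ly$", wi)) {
      lemma[i] <- wi; upos[i] <- "ADV"; deprel[i] <- "advmod"
    } else if (nchar(wi) > 4L && grepl("(ing|ed)$", wi)) {
      lemma[i] <- heuristic_lemma(wi); upos[i] <- "VERB"; deprel[i] <- "root"
    } else {
      lemma[i] <- heuristic_lemma(wi); upos[i] <- "NOUN"; deprel[i] <- "obj"
    }
  }
  tibble::tibble(lemma = lemma, upos = upos, deprel = deprel)
}

#' Annotate a transcript sample
#'
#' Fills the `lemma`, `upos` and `deprel` fields of every token using a
#' registered tagger. Token order and count are never altered; a tagger
#' returning the wrong number of labels is an error.
#'
#' @param sample A [transcript_sample()].
#' @param tagger Tagger name (see [register_tagger()]) or an annotation
#'   function.
#' @param overwrite If `FALSE` (default) an already fully annotated sample is
#'   returned unchanged.
#' @return The annotated sample.
#' @export
annotate_sample <- function(sample, tagger = "fallback", overwrite = FALSE) {
  if (nrow(sample$tokens) == 0L) return(sample)
  if (!overwrite && is_annotated(sample)) return(sample)
  fn <- if (is.function(tagger)) tagger else get_tagger(tagger)
  ann <- fn(sample$tokens$text)
  if (nrow(ann) != nrow(sample$tokens)) {
    stop("tagger returned ", nrow(ann), " label rows for ",
         nrow(sample$tokens), " tokens", call. = FALSE)
  }
  sample$tokens$lemma <- tolower(as.character(ann$lemma))
  sample$tokens$upos <- as.character(ann$upos)
  sample$tokens$deprel <- as.character(ann$deprel)
  sample
}

content_upos <- c("NOUN", "VERB", "ADJ", "ADV")

#' Is a token a content word?
#'
#' Content words are exactly the four open lexical classes of the universal
#' POS inventory: `NOUN`, `VERB`, `ADJ`, `ADV`. Auxiliaries (`AUX`) and
#' proper nouns (`PROPN`) are separate universal classes and are excluded.
#'
#' @param upos Character vector of universal POS tags (e.g. the `upos`
#'   column of a sample's tokens).
#' @return Logical vector.
#' @export
is_content_word <- function(upos) {
  if (anyNA(upos)) {
    stop("unannotated token: upos is missing; run annotate_sample() first",
         call. = FALSE)
  }
  upos %in% content_upos
}
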