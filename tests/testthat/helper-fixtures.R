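# Small in-code fixtures shared across the suite.

tiny_dict <- function() {
  cu_dictionary(
    list(girl = c("girl", "daughter"),
         basket = c("basket"),
         fisherman = c("fisherman", "fishing pole"),
         picnic = c("picnic")),
    theme_unit = "picnic"
  )
}

tiny_lexicon <- function() {
  frequency_lexicon(
    c(dog = 403, cat = 100, tree = 1000, girl = 500, basket = 200,
      picnic = 300, fisherman = 50, gem = 25, bed = 900, find = 150),
    corpus_total = 10000
  )
}

# Build a sample from parallel vectors; annotation columns optional.
make_sample <- function(words, starts, ends, lemma = NULL, upos = NULL,
                        deprel = NULL, id = "p1", group = "PCA",
                        task = "picture") {
  tok <- tibble::tibble(text = words, start = starts, end = ends)
  if (!is.null(lemma)) tok$lemma <- lemma
  if (!is.null(upos)) tok$upos <- upos
  if (!is.null(deprel)) tok$deprel <- deprel
  transcript_sample(id, group, task, tok)
}

# Evenly timed sample annotated by the fallback tagger.
tagged_sample <- function(words, id = "p1", group = "PCA") {
  n <- length(words)
  s <- make_sample(words, starts = seq(0, by = 0.5, length.out = n),
                   ends = seq(0.4, by = 0.5, length.out = n),
                   id = id, group = group)
  annotate_sample(s)
}

# Independent penalized-logistic oracle: BFGS on the penalized log-likelihood.
optim_logistic <- function(X, y, ridge) {
  Z <- cbind(1, as.matrix(X))
  pen <- c(0, rep(ridge, ncol(Z) - 1L))
  nll <- function(b) {
    eta <- drop(Z %*% b)
    -(sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2)
  }
  gr <- function(b) {
    eta <- drop(Z %*% b)
    -(drop(crossprod(Z, y - plogis(eta))) - pen * b)
  }
  opt <- optim(numeric(ncol(Z)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}
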