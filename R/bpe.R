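#' Train a byte-pair-encoding sub-token codec
#'
#' Builds a deliberately small sub-token vocabulary over the symbolic
#' location corpus by iteratively merging the most frequent adjacent symbol
#' pair. A small budget (200 for the full-store configuration) forces each
#' role+location word to decompose into a few reusable sub-tokens, which is
#' what lets the sequence model generalise across locations sharing quadrant
#' prefixes instead of memorising whole cells.
#'
#' Properties guaranteed here: merges never cross whitespace (words are the
#' merge universe); the placeholder and end-of-trajectory words are seeded as
#' atomic symbols; training is deterministic — pair counts tie-break
#' lexicographically — so the same corpus and budget always give the same
#' merge list; encoding then decoding any document built from the training
#' alphabet reproduces it exactly.
#'
#' @param corpus A list of documents (from [build_corpus()]) or a character
#'   vector of document texts.
#' @param vocab_budget Total vocabulary size (base symbols + merges).
#' @param cfg A [corpus_config()]; its absent/end words are seeded atomic.
#' @param grid Optional [grid_spec()]; when given, the base alphabet is
#'   seeded with every quadrant letter the grid can produce (plus the role
#'   prefixes), so all well-formed words are encodable even if some cells
#'   were never visited in the training corpus.
#' @param seed Ignored (training is deterministic); accepted for interface
#'   uniformity with the other training entry points.
#' @return An object of class `subtoken_codec`: `vocab` (character vector;
#'   integer id = position), `merges` (data.frame `a`, `b`), `atoms`.
#' @export
train_codec <- function(corpus, vocab_budget = 200L, cfg = corpus_config(),
                        grid = NULL, seed = NULL) {
  texts <- if (is.list(corpus) && !is.null(corpus[[1L]]$text))
    vapply(corpus, `[[`, character(1L), "text") else as.character(corpus)
  if (length(texts) == 0L || all(!nzchar(texts)))
    stop("corpus is empty", call. = FALSE)
  atoms <- c(paste0(cfg$role_prefixes[-1L], cfg$absent_token), cfg$eos_token)

  words <- unlist(strsplit(trimws(texts), "\\s+"), use.names = FALSE)
  wf <- table(words)
  word_strs <- names(wf)
  freqs <- as.integer(wf)
  # symbol sequences per distinct word; atomic words are single symbols
  seqs <- lapply(word_strs, function(w) {
    if (w %in% atoms) w else strsplit(w, "", fixed = TRUE)[[1L]]
  })

  base <- unique(unlist(seqs, use.names = FALSE))
  if (!is.null(grid))
    base <- unique(c(base, cfg$role_prefixes,
                     unlist(lapply(seq_len(grid$depth), level_block))))
  base <- sort(base)
  if (vocab_budget < length(base))
    stop(sprintf("vocab_budget %d smaller than base alphabet of %d symbols",
                 vocab_budget, length(base)), call. = FALSE)
  vocab <- base
  merges_a <- character(0); merges_b <- character(0)

  while (length(vocab) < vocab_budget) {
    # count adjacent pairs weighted by word frequency
    counts <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      if (length(s) < 2L) next
      pl <- paste(s[-length(s)], s[-1L], sep = "\r")
      for (p in pl) {
        prev <- counts[[p]]
        counts[[p]] <- if (is.null(prev)) freqs[i] else prev + freqs[i]
      }
    }
    keys <- ls(counts)
    if (length(keys) == 0L) break
    vals <- vapply(keys, function(k) counts[[k]], numeric(1L))
    best <- keys[vals == max(vals)]
    best <- sort(best)[1L]  # deterministic tie-break: lexicographic
    ab <- strsplit(best, "\r", fixed = TRUE)[[1L]]
    merged <- paste0(ab[1L], ab[2L])
    merges_a <- c(merges_a, ab[1L]); merges_b <- c(merges_b, ab[2L])
    vocab <- c(vocab, merged)
    seqs <- lapply(seqs, merge_pair_in_seq, a = ab[1L], b = ab[2L],
                   merged = merged)
  }

  codec <- structure(
    list(vocab = vocab, merges = data.frame(a = merges_a, b = merges_b),
         atoms = atoms),
    class = "subtoken_codec"
  )
  codec$cache <- new.env(hash = TRUE, parent = emptyenv())
  codec
}

merge_pair_in_seq <- function(s, a, b, merged) {
  if (length(s) < 2L) return(s)
  i <- 1L; out <- character(0)
  while (i <= length(s)) {
    if (i < length(s) && s[i] == a && s[i + 1L] == b) {
      out <- c(out, merged); i <- i + 2L
    } else {
      out <- c(out, s[i]); i <- i + 1L
    }
  }
  out
}

#' @export
print.subtoken_codec <- function(x, ...) {
  cat(sprintf("<subtoken_codec> vocab %d (%d merges, %d atoms)\n",
              length(x$vocab), nrow(x$merges), length(x$atoms)))
  invisible(x)
}

# encode one word to sub-token ids, memoised on the codec's cache
encode_word <- function(word, codec) {
  hit <- codec$cache[[word]]
  if (!is.null(hit)) return(hit)
  if (word %in% codec$atoms) {
    s <- word
  } else {
    s <- strsplit(word, "", fixed = TRUE)[[1L]]
    for (m in seq_len(nrow(codec$merges))) {
      a <- codec$merges$a[m]; b <- codec$merges$b[m]
      if (length(s) < 2L) break
      if (any(s[-length(s)] == a & s[-1L] == b))
        s <- merge_pair_in_seq(s, a, b, paste0(a, b))
    }
  }
  ids <- match(s, codec$vocab)
  if (anyNA(ids))
    stop(sprintf("word '%s' contains symbols outside the codec alphabet", word),
         call. = FALSE)
  codec$cache[[word]] <- ids
  ids
}

#' Encode a document's words into sub-token ids
#'
#' @param words Character vector of words (whitespace-split document).
#' @param codec A [train_codec()] codec.
#' @return A list with `ids` (integer vector over the whole document) and
#'   `word_of` (integer: which word each sub-token belongs to).
#' @export
encode_words <- function(words, codec) {
  per <- lapply(words, encode_word, codec = codec)
  list(ids = unlist(per, use.names = FALSE),
       word_of = rep(seq_along(words), lengths(per)))
}

#' Decode sub-token ids back to document text
#'
#' Word boundaries are recovered from the grammar: every word starts with an
#' uppercase role prefix (or is an atomic reserved word), while location code
#' characters are lowercase; a space is inserted before each uppercase start.
#'
#' @param ids Integer sub-token ids.
#' @param codec A [train_codec()] codec.
#' @return The decoded text (single-space separated words).
#' @export
decode_ids <- function(ids, codec) {
  if (length(ids) == 0L) return("")
  if (any(ids < 1L | ids > length(codec$vocab)))
    stop("sub-token id out of vocabulary range", call. = FALSE)
  syms <- codec$vocab[ids]
  starts <- grepl("^[A-Z]", syms)
  starts[1L] <- TRUE
  paste(tapply(syms, cumsum(starts), paste, collapse = ""), collapse = " ")
}

#' Report the sub-token decomposition of every role word
#'
#' The small vocabulary is meant to split each role+location word into a
#' handful of reusable sub-tokens (the design goal is 2-4 on the full-store
#' configuration) rather than memorise whole words. This audit computes the
#' decomposition length of every distinct word in a corpus and flags
#' violations of the target band; violations are reported, never silently
#' accepted.
#'
#' @param codec A [train_codec()] codec.
#' @param corpus Documents or texts whose words to audit.
#' @param bounds Target band for sub-tokens per word (atomic reserved words
#'   are exempt).
#' @return A list: `per_word` (data.frame `word`, `n_subtokens`), `min`,
#'   `max`, `mean`, `in_bounds`, `violations` (words outside the band).
#' @export
decomposition_report <- function(codec, corpus, bounds = c(2L, 4L)) {
  texts <- if (is.list(corpus) && !is.null(corpus[[1L]]$text))
    vapply(corpus, `[[`, character(1L), "text") else as.character(corpus)
  words <- setdiff(unique(unlist(strsplit(trimws(texts), "\\s+"))), codec$atoms)
  n <- vapply(words, function(w) length(encode_word(w, codec)), integer(1L))
  per_word <- data.frame(word = words, n_subtokens = unname(n))
  viol <- per_word$word[n < bounds[1L] | n > bounds[2L]]
  if (length(viol) > 0L)
    warning(sprintf("%d of %d words decompose outside [%d, %d] sub-tokens (e.g. %s)",
                    length(viol), length(words), bounds[1L], bounds[2L],
                    paste(utils::head(viol, 3L), collapse = ", ")),
            call. = FALSE)
  list(per_word = per_word, min = min(n), max = max(n), mean = mean(n),
       in_bounds = length(viol) == 0L, violations = viol)
}

#' Serialise / load a codec as JSON
#'
#' @param codec A `subtoken_codec`.
#' @param path File path.
#' @export
write_codec <- function(codec, path) {
  jsonlite::write_json(
    list(vocab = codec$vocab,
         merges = codec$merges,
         atoms = codec$atoms),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_codec
#' @export
read_codec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  codec <- structure(
    list(vocab = as.character(x$vocab),
         merges = if (length(x$merges) == 0L)
           data.frame(a = character(0), b = character(0))
         else as.data.frame(x$merges),
         atoms = as.character(x$atoms)),
    class = "subtoken_codec"
  )
  codec$cache <- new.env(hash = TRUE, parent = emptyenv())
  codec
}

#' Encode a document with its asymmetric loss mask
#'
#' Converts a document into the sub-token id sequence the model trains on,
#' plus the boolean target mask implementing asymmetric loss masking:
#' `target_mask[i]` is `TRUE` iff the label predicted from the prefix ending
#' at position `i` — i.e. the sub-token at position `i + 1` — belongs to a
#' focal-role (`S`) word or is the end-of-trajectory word. Neighbour (`O`,
#' `T`, `U`) sub-tokens condition the model but never supervise it. The last
#' position has no label and is always masked out.
#'
#' @param doc A [build_document()] document.
#' @param codec A [train_codec()] codec.
#' @param cfg The [corpus_config()] used to build the document.
#' @return An object of class `masked_example`: `ids`, `target_mask`,
#'   `word_of`, `roles` (per sub-token), `frame_starts` (id positions where
#'   each `1+k`-word frame begins).
#' @export
encode_with_mask <- function(doc, codec, cfg) {
  enc <- encode_words(doc$words, codec)
  roles <- doc$spans$role[enc$word_of]
  n <- length(enc$ids)
  label_role <- c(roles[-1L], NA)
  mask <- !is.na(label_role) &
    (label_role == cfg$role_prefixes[1L] | label_role == "eos")
  arity <- cfg$k + 1L
  first_words <- seq(1L, length(doc$words), by = arity)
  first_words <- first_words[doc$spans$role[first_words] == cfg$role_prefixes[1L]]
  frame_starts <- match(first_words, enc$word_of)
  structure(
    list(ids = enc$ids, target_mask = mask, word_of = enc$word_of,
         roles = roles, frame_starts = frame_starts),
    class = "masked_example"
  )
}
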