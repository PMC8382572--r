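## Stimulus-sequence generators for the two auditory paradigms:
## an oddball tone stream (frequent standards, rare deviants) and
## prime-target spoken word pairs (half semantically congruent).

#' Generate an oddball tone sequence
#'
#' Emits `nStimuli` tone events at a fixed inter-stimulus interval, of which
#' `round(deviantFraction * nStimuli)` are deviants. The deviant positions
#' are pseudorandomized under the constraint that no two deviants are
#' adjacent (possible whenever the deviant count is at most half the stream;
#' otherwise placement falls back to unconstrained sampling with a warning).
#'
#' @param nStimuli number of tones (>= 1).
#' @param deviantFraction proportion of deviants in `[0, 1]`; default 0.2,
#'   the classic 80/20 oddball ratio.
#' @param isi inter-stimulus onset interval in seconds (> 0).
#' @param seed RNG seed for the deviant placement (optional).
#' @param noAdjacentDeviants enforce the adjacency constraint (default TRUE).
#' @return A [StimulusSequence-class] of tone events; first onset at `isi`.
#' @export
#' @examples
#' s <- generateToneSequence(600, 0.2, isi = 1, seed = 1)
#' table(events(s)$condition)
generateToneSequence <- function(nStimuli, deviantFraction = 0.2, isi = 1,
                                 seed = NULL, noAdjacentDeviants = TRUE) {
  stopifnot_scalar(nStimuli, "nStimuli", lower = 1)
  stopifnot_scalar(deviantFraction, "deviantFraction", lower = 0, upper = 1)
  if (!is.numeric(isi) || length(isi) != 1L || !is.finite(isi) || isi <= 0)
    stop("'isi' must be a single positive number")
  nStimuli <- as.integer(nStimuli)
  nDev <- as.integer(round(deviantFraction * nStimuli))
  withSeed(seed, {
    if (nDev == 0L) {
      pos <- integer(0)
    } else if (noAdjacentDeviants && nDev <= (nStimuli + 1L) %/% 2L) {
      ## uniform sample of non-adjacent position sets: choose nDev slots from
      ## nStimuli - nDev + 1 and spread them apart by one each
      pos <- sort(sample.int(nStimuli - nDev + 1L, nDev)) + seq_len(nDev) - 1L
    } else {
      if (noAdjacentDeviants)
        warning("deviant fraction too high for the adjacency constraint; ",
                "placing deviants without it")
      pos <- sort(sample.int(nStimuli, nDev))
    }
    kind <- rep("standard_tone", nStimuli)
    kind[pos] <- "deviant_tone"
    StimulusSequence(data.frame(
      onset = isi * seq_len(nStimuli),
      kind = kind,
      condition = ifelse(kind == "deviant_tone", "deviant", "standard"),
      stringsAsFactors = FALSE))
  })
}

#' Built-in prime/target word-pair lexicon
#'
#' A small lexicon of semantic-priming triples: a prime word, a strongly
#' associated (congruent) target and an unrelated (incongruent) target. The
#' incongruent target of each row is the congruent target of another row, so
#' the target vocabulary is identical across conditions. If more than the
#' built-in number of rows is requested, additional synthetic triples
#' (`primeNN`/`targetNN`) are appended.
#'
#' @param n minimum number of rows required (default: the full built-in set).
#' @return data.frame with columns `prime`, `congruent_target`,
#'   `incongruent_target`.
#' @export
defaultLexicon <- function(n = NULL) {
  primes <- c("bread", "salt", "cat", "doctor", "table", "king", "sun", "shoe",
              "rain", "coffee", "pen", "night", "winter", "hand", "tooth",
              "river", "apple", "bird", "fire", "door", "milk", "sleep",
              "grass", "ocean", "music", "knife", "cloud", "honey", "letter",
              "chair", "snow", "lamp", "mountain", "clock", "flower", "paper",
              "shirt", "storm", "sugar", "train", "wolf", "garden", "mirror",
              "candle", "bridge", "forest", "needle", "soldier", "window",
              "butter2", "spoon", "rocket", "violin", "anchor", "desert",
              "helmet", "ladder", "magnet", "pillow", "ribbon")
  targets <- c("butter", "pepper", "dog", "nurse", "chair2", "queen", "moon",
               "sock", "umbrella", "cup", "ink", "day", "summer", "finger",
               "brush", "bank", "pie", "nest", "smoke", "key", "cow", "dream",
               "green", "wave", "song", "fork", "sky", "bee", "stamp", "seat",
               "ice", "light", "valley", "time", "bee2", "pencil", "button",
               "thunder", "sweet", "track", "howl", "rose", "glass", "flame",
               "water", "tree", "thread", "army", "glass2", "toast", "bowl",
               "space", "bow2", "ship", "sand", "head", "step", "iron",
               "bed", "bow")
  stopifnot(length(primes) == length(targets))
  k <- length(primes)
  if (!is.null(n) && n > k) {
    extra <- n - k
    primes <- c(primes, sprintf("prime%02d", seq_len(extra)))
    targets <- c(targets, sprintf("target%02d", seq_len(extra)))
    k <- length(primes)
  }
  ## incongruent target: the congruent target of the next row (a derangement)
  data.frame(prime = primes,
             congruent_target = targets,
             incongruent_target = targets[c(2:k, 1L)],
             stringsAsFactors = FALSE)
}

#' Generate a prime-target word-pair sequence
#'
#' Emits `nPairs` spoken word pairs: a prime followed by a target after
#' `soa` seconds, with pair onsets `pairPeriod` seconds apart. A fraction
#' `congruentFraction` of the targets (count = `round(f * nPairs)`) are the
#' prime's associated word; the remainder are unrelated. A different seed
#' yields a different pseudorandomized arrangement of pairs and conditions,
#' emulating a retest with fresh word-pair orderings.
#'
#' @param nPairs number of prime-target pairs.
#' @param congruentFraction proportion of congruent pairs (default 0.5).
#' @param seed RNG seed (optional).
#' @param lexicon data.frame as returned by [defaultLexicon()]; must have at
#'   least `nPairs` rows.
#' @param soa prime-to-target onset asynchrony in seconds.
#' @param pairPeriod onset-to-onset interval between successive pairs (s).
#' @return A [StimulusSequence-class] of `word_prime`/`word_target` events.
#' @export
generateWordPairSequence <- function(nPairs, congruentFraction = 0.5,
                                     seed = NULL,
                                     lexicon = defaultLexicon(nPairs),
                                     soa = 1, pairPeriod = 3) {
  stopifnot_scalar(nPairs, "nPairs", lower = 1)
  stopifnot_scalar(congruentFraction, "congruentFraction", 0, 1)
  if (nrow(lexicon) < nPairs)
    stop(sprintf("lexicon has %d rows but %d pairs requested",
                 nrow(lexicon), nPairs))
  if (soa <= 0 || pairPeriod <= soa)
    stop("need 0 < soa < pairPeriod")
  nPairs <- as.integer(nPairs)
  nCon <- as.integer(round(congruentFraction * nPairs))
  withSeed(seed, {
    rows <- sample.int(nrow(lexicon), nPairs)
    congruent <- rep(FALSE, nPairs)
    congruent[sample.int(nPairs, nCon)] <- TRUE
    lex <- lexicon[rows, ]
    primeOn <- pairPeriod * (seq_len(nPairs) - 1L) + 1
    ev <- data.frame(
      onset = as.vector(rbind(primeOn, primeOn + soa)),
      kind = rep(c("word_prime", "word_target"), nPairs),
      condition = as.vector(rbind(rep("none", nPairs),
                                  ifelse(congruent, "congruent", "incongruent"))),
      word = as.vector(rbind(lex$prime,
                             ifelse(congruent, lex$congruent_target,
                                    lex$incongruent_target))),
      stringsAsFactors = FALSE)
    StimulusSequence(ev)
  })
}
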