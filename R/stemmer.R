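# Porter's suffix-stripping stemmer (1980 algorithm), implemented from the
# published rule tables. Words shorter than 3 letters are returned unchanged.

.pstem_isCons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pstem_isCons(chars, i - 1L))
  }
  TRUE
}

.pstem_consMask <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mask <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      mask[i] <- FALSE
    } else if (ch == "y") {
      mask[i] <- if (i == 1L) TRUE else !mask[i - 1L]
    } else {
      mask[i] <- TRUE
    }
  }
  mask
}

# the measure m in the form C?(VC)^m V?
.pstem_m <- function(word) {
  if (!nchar(word)) return(0L)
  mask <- .pstem_consMask(word)
  m <- 0L
  seenVowel <- FALSE
  for (cons in mask) {
    if (!cons) {
      seenVowel <- TRUE
    } else if (seenVowel) {
      m <- m + 1L
      seenVowel <- FALSE
    }
  }
  m
}

.pstem_hasVowel <- function(word) {
  nchar(word) > 0 && any(!.pstem_consMask(word))
}

.pstem_endsDouble <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && .pstem_consMask(word)[n]
}

# *o: stem ends consonant-vowel-consonant, final consonant not w, x or y
.pstem_endsCVC <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  mask <- .pstem_consMask(word)
  last <- substr(word, n, n)
  mask[n - 2L] && !mask[n - 1L] && mask[n] && !last %in% c("w", "x", "y")
}

.pstem_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) && endsWith(word, suffix)
}

.pstem_chop <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

.pstem_step1a <- function(w) {
  if (.pstem_ends(w, "sses")) return(paste0(.pstem_chop(w, "sses"), "ss"))
  if (.pstem_ends(w, "ies")) return(paste0(.pstem_chop(w, "ies"), "i"))
  if (.pstem_ends(w, "ss")) return(w)
  if (.pstem_ends(w, "s")) return(.pstem_chop(w, "s"))
  w
}

.pstem_step1b <- function(w) {
  if (.pstem_ends(w, "eed")) {
    stem <- .pstem_chop(w, "eed")
    if (.pstem_m(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  touched <- FALSE
  if (.pstem_ends(w, "ed") && .pstem_hasVowel(.pstem_chop(w, "ed"))) {
    w <- .pstem_chop(w, "ed"); touched <- TRUE
  } else if (.pstem_ends(w, "ing") && .pstem_hasVowel(.pstem_chop(w, "ing"))) {
    w <- .pstem_chop(w, "ing"); touched <- TRUE
  }
  if (touched) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pstem_endsDouble(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.pstem_m(w) == 1L && .pstem_endsCVC(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.pstem_step1c <- function(w) {
  if (.pstem_ends(w, "y") && .pstem_hasVowel(.pstem_chop(w, "y")))
    return(paste0(.pstem_chop(w, "y"), "i"))
  w
}

.pstem_rules2 <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
  c("biliti", "ble"), c("ation", "ate"), c("alism", "al"),
  c("aliti", "al"), c("iviti", "ive"), c("ousli", "ous"),
  c("entli", "ent"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("eli", "e"))

.pstem_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))

.pstem_mapRules <- function(w, rules, minM) {
  for (r in rules) {
    if (.pstem_ends(w, r[1])) {
      stem <- .pstem_chop(w, r[1])
      if (.pstem_m(stem) > minM - 1L) return(paste0(stem, r[2]))
      return(w) # first matching suffix decides; no fallthrough
    }
  }
  w
}

.pstem_suffixes4 <- c("ement", "ance", "ence", "able", "ible", "ment",
                      "ant", "ent", "ion", "ism", "ate", "iti", "ous",
                      "ive", "ize", "al", "er", "ic", "ou")

.pstem_step4 <- function(w) {
  for (s in .pstem_suffixes4) {
    if (.pstem_ends(w, s)) {
      stem <- .pstem_chop(w, s)
      ok <- .pstem_m(stem) > 1L
      if (s == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) return(stem)
      return(w)
    }
  }
  w
}

.pstem_step5 <- function(w) {
  if (endsWith(w, "e") && nchar(w) > 1L) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- .pstem_m(stem)
    if (m > 1L || (m == 1L && !.pstem_endsCVC(stem))) w <- stem
  }
  if (.pstem_m(w) > 1L && .pstem_endsDouble(w) && endsWith(w, "l"))
    w <- substr(w, 1L, nchar(w) - 1L)
  w
}

#' Porter stemmer
#'
#' Reduces English words to their stems with Porter's 1980 suffix-stripping
#' algorithm (e.g. "apoptotic" -> "apoptot", "processes" -> "process").
#' Deterministic; words shorter than three letters pass through unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porterStem(c("apoptotic", "processes", "signaling"))
#' @export
porterStem <- function(words) {
  vapply(words, function(w) {
    if (is.na(w) || nchar(w) < 3L) return(w)
    w <- .pstem_step1a(w)
    w <- .pstem_step1b(w)
    w <- .pstem_step1c(w)
    w <- .pstem_mapRules(w, .pstem_rules2, minM = 1L)
    w <- .pstem_mapRules(w, .pstem_rules3, minM = 1L)
    w <- .pstem_step4(w)
    .pstem_step5(w)
  }, character(1), USE.NAMES = FALSE)
}
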