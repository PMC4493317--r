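#' Construct a wordlist for one language variety
#'
#' A wordlist maps concepts to one or more word forms for a single variety,
#' optionally with a cognate-class identifier per form. Cognate coding is
#' all-or-none: either every form of the variety carries a class or none
#' does — mixed coding is rejected, because a partially coded variety cannot
#' enter the shared-cognate distance coherently.
#'
#' Forms are Unicode strings compared at the level of code points after NFC
#' normalization (applied here, once, so downstream distance code can treat
#' forms as plain symbol sequences).
#'
#' @param variety_id single string naming the variety.
#' @param forms named list, concept id -> character vector of forms
#'   (synonyms allowed); every concept must have at least one non-empty
#'   form.
#' @param cognates `NULL` (uncoded) or a named list parallel to `forms`
#'   giving one cognate-class id per form.
#' @return An object of class `wordlist`.
#' @examples
#' w <- wordlist("mandarin_beijing",
#'               forms = list(hand = "b7u", water = "šui"),
#'               cognates = list(hand = "H1", water = "W1"))
#' w
#' @export
wordlist <- function(variety_id, forms, cognates = NULL) {
  stopifnot(is.character(variety_id), length(variety_id) == 1L,
            nzchar(variety_id))
  if (!is.list(forms) || is.null(names(forms)) || any(!nzchar(names(forms))))
    stop("'forms' must be a named list (concept id -> character forms)")
  if (anyDuplicated(names(forms)))
    stop("duplicate concept ids in wordlist for variety '", variety_id, "'")
  forms <- lapply(forms, function(f) {
    f <- as.character(f)
    if (length(f) < 1L || any(is.na(f)) || any(!nzchar(f)))
      stop("every concept needs at least one non-empty form (variety '",
           variety_id, "')")
    stringi::stri_trans_nfc(f)
  })
  if (!is.null(cognates)) {
    if (!is.list(cognates) || !setequal(names(cognates), names(forms)))
      stop("'cognates' must be a named list over the same concepts as ",
           "'forms' (variety '", variety_id, "')")
    cognates <- cognates[names(forms)]
    ok <- mapply(function(f, k) length(k) == length(f) &&
                   !any(is.na(k)) && all(nzchar(as.character(k))),
                 forms, cognates)
    if (!all(ok))
      stop("cognate classes must parallel forms one-to-one (variety '",
           variety_id, "', concept(s) ",
           paste(names(forms)[!ok], collapse = ", "), ")")
    cognates <- lapply(cognates, as.character)
  }
  structure(list(variety_id = variety_id, forms = forms,
                 cognates = cognates),
            class = "wordlist")
}

#' @export
print.wordlist <- function(x, ...) {
  cat("<wordlist> variety:", x$variety_id, "|", length(x$forms),
      "concepts |", if (is.null(x$cognates)) "no cognate coding"
      else "cognate-coded", "\n")
  invisible(x)
}

#' Concepts present in a wordlist
#' @param w a [wordlist].
#' @return character vector of concept ids.
#' @export
concepts <- function(w) {
  stopifnot(inherits(w, "wordlist"))
  names(w$forms)
}

has_cognates <- function(w) !is.null(w$cognates)
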