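# Phonological attribute inventory and canonical phone -> attribute map.
#
# Phone attribute (distinctive-feature) analysis describes each speech sound
# by a small set of binary articulatory properties (voiced, fricative,
# coronal, ...).  The classifiers in this package operate on per-frame
# posterior probabilities over 21 such classes: 20 distinctive features in
# the Chomsky-Halle tradition plus an explicit "silence" class.  The exact
# 20-name inventory is a package choice; it contains every attribute the
# method's interpretation relies on (continuant, tense, voiced, fricative,
# retroflex, velar, high, coronal, mid, back, vocalic, anterior, labial).

#' Phonological attribute names
#'
#' The fixed 21-class inventory used throughout the package: 20 binary
#' distinctive features plus `"silence"`.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' pd_attributes()
pd_attributes <- function() {
  c("silence", "consonantal", "vocalic", "continuant", "voiced", "tense",
    "fricative", "strident", "nasal", "lateral", "retroflex", "anterior",
    "coronal", "labial", "high", "mid", "low", "back", "round",
    "approximant", "velar")
}

# Active-attribute sets per phone.  The inventory is deliberately coarse: it
# only has to give each speech protocol a distinct phone-diversity profile
# and give structurally dependent attribute pairs (e.g. high/coronal within
# the pataka phone set) their canonical co-activation.
phone_inventory <- function() {
  list(
    sil = c("silence"),
    a = c("vocalic", "continuant", "voiced", "tense", "low", "back",
          "approximant"),
    e = c("vocalic", "continuant", "voiced", "tense", "mid", "anterior",
          "approximant"),
    i = c("vocalic", "continuant", "voiced", "tense", "high", "anterior",
          "approximant"),
    o = c("vocalic", "continuant", "voiced", "tense", "mid", "back",
          "round", "approximant"),
    u = c("vocalic", "continuant", "voiced", "tense", "high", "back",
          "round", "approximant"),
    p = c("consonantal", "labial", "anterior", "tense", "round"),
    t = c("consonantal", "coronal", "anterior", "high", "tense"),
    k = c("consonantal", "velar", "back", "tense"),
    b = c("consonantal", "labial", "anterior", "voiced", "round"),
    d = c("consonantal", "coronal", "anterior", "high", "voiced"),
    g = c("consonantal", "velar", "back", "voiced"),
    m = c("consonantal", "nasal", "labial", "anterior", "voiced"),
    n = c("consonantal", "nasal", "coronal", "anterior", "voiced"),
    l = c("consonantal", "lateral", "coronal", "anterior", "voiced",
          "continuant", "approximant"),
    r = c("consonantal", "retroflex", "back", "voiced", "continuant",
          "approximant"),
    s = c("consonantal", "fricative", "strident", "coronal", "anterior",
          "continuant", "tense"),
    z = c("consonantal", "fricative", "strident", "coronal", "anterior",
          "continuant", "voiced"),
    S = c("consonantal", "fricative", "strident", "coronal", "high",
          "round", "continuant"),
    f = c("consonantal", "fricative", "labial", "anterior", "continuant",
          "tense"),
    v = c("consonantal", "fricative", "labial", "anterior", "continuant",
          "voiced"),
    h = c("fricative", "continuant", "low"),
    w = c("approximant", "labial", "back", "round", "voiced", "continuant"),
    j = c("approximant", "high", "anterior", "voiced", "continuant")
  )
}

#' Canonical phone-to-attribute map
#'
#' Maps every phone of the synthesis inventory to its canonical 21-bit
#' binary attribute vector. The `sil` phone activates only `"silence"`.
#'
#' @return A list with elements `attributes` (character, length 21) and
#'   `phones` (named list of 0/1 integer vectors of length 21).
#' @export
#' @examples
#' m <- phone_attribute_map()
#' m$phones$a[m$attributes == "vocalic"]  # 1
phone_attribute_map <- function() {
  attrs <- pd_attributes()
  inv <- phone_inventory()
  phones <- lapply(inv, function(act) {
    bad <- setdiff(act, attrs)
    if (length(bad)) stopf("unknown attribute(s): %s", paste(bad, collapse = ", "))
    as.integer(attrs %in% act)
  })
  structure(list(attributes = attrs, phones = phones),
            class = "phone_attribute_map")
}

# Phone sequences per speech protocol.  Words are separated by "sil".  The
# sequences are simplified renderings of the elicitation tasks (counting,
# month naming, sustained vowels, /pataka/-type diadochokinesis, tongue
# twisters, a reading passage, a monologue); only their relative length and
# phone diversity matter downstream.
protocol_templates <- function() {
  wrd <- function(...) c(unlist(strsplit(c(...), " ")), "sil")
  digits <- c(
    wrd("a i n s"), wrd("t s v a i"), wrd("d r a i"), wrd("f i r"),
    wrd("f i n f"), wrd("z e k s"), wrd("z i b e n"), wrd("a k t"),
    wrd("n o i n"), wrd("t s e n"))
  months <- c(
    wrd("j a n u a r"), wrd("f e b r u a r"), wrd("m e r t s"),
    wrd("a p r i l"), wrd("m a i"), wrd("j u n i"), wrd("j u l i"),
    wrd("a u g u s t"), wrd("s e p t e m b e r"), wrd("o k t o b e r"),
    wrd("n o v e m b e r"), wrd("d e t s e m b e r"))
  vowels <- c(wrd("a a"), wrd("e e"), wrd("i i"), wrd("o o"), wrd("u u"))
  pataka <- c(
    wrd("p a t a k a"), wrd("p a k a t a"), wrd("p e t a k a"),
    wrd("p e k a t a"))
  twisters <- c(
    wrd("l i b e"), wrd("l i l i"), wrd("l e m a n"),
    wrd("d r i t e"), wrd("b e r i t e n e"), wrd("k a v a l e r i"),
    wrd("b r i g a d e"),
    wrd("S l a i m i g"), wrd("S u p e n d e"), wrd("S e l f i S"),
    wrd("f l o s e n"))
  read <- c(
    wrd("a i n e s"), wrd("t a g e s"), wrd("g i n g"), wrd("d e r"),
    wrd("m a n"), wrd("m i t"), wrd("z a i n e m"), wrd("h u n t"),
    wrd("d u r k"), wrd("d e n"), wrd("v a l t"), wrd("u n d"),
    wrd("z a h"), wrd("f o g e l"), wrd("a m"), wrd("h i m e l"),
    wrd("f l i g e n"), wrd("d a n"), wrd("k a m"), wrd("r e g e n"))
  monologue <- c(
    wrd("d a s"), wrd("b i l t"), wrd("t s a i k t"), wrd("a i n e"),
    wrd("k y k e"), wrd("a i n"), wrd("j u n g e"), wrd("S t e t"),
    wrd("a u f"), wrd("a i n e m"), wrd("h o k e r"), wrd("u n d"),
    wrd("n i m t"), wrd("k e k s e"), wrd("a u s"), wrd("d e r"),
    wrd("d o z e"), wrd("d i"), wrd("m u t e r"), wrd("S p y l t"),
    wrd("g e S i r"), wrd("v a s e r"), wrd("l o i f t"),
    wrd("y b e r"), wrd("d e n"), wrd("b o d e n"))
  # phones not in the inventory (y, x, ...) are mapped to close ones
  fix <- function(x) { x[x == "y"] <- "u"; x[x == "x"] <- "k"; x }
  lapply(list(digits = digits, months = months, vowels = vowels,
              pataka = pataka, twisters = twisters, read = read,
              monologue = monologue), fix)
}

#' Names of the seven speech protocols
#' @return Character vector of protocol names.
#' @export
pd_protocols <- function() names(protocol_templates())

# Articulatory confusion partners: when OFF-state weakening suppresses an
# attribute, the misarticulated segment may activate this (normally
# inactive) partner instead — slurring substitutes, it does not simply
# delete.  Silence has no partner and is never weakened.
attribute_confusion_map <- function() {
  c(consonantal = "vocalic", vocalic = "nasal", continuant = "consonantal",
    voiced = "tense", tense = "voiced", fricative = "approximant",
    strident = "lateral", nasal = "vocalic", lateral = "strident",
    retroflex = "high", anterior = "velar", coronal = "labial",
    labial = "coronal", high = "mid", mid = "high", low = "mid",
    back = "round", round = "low", approximant = "nasal",
    velar = "anterior")
}

# Base phone durations in 10-ms frames, by articulatory class.
phone_base_frames <- function(phone) {
  vowels <- c("a", "e", "i", "o", "u")
  fric <- c("s", "z", "S", "f", "v", "h")
  if (phone == "sil") 9L
  else if (phone %in% vowels) 11L
  else if (phone %in% fric) 8L
  else if (phone %in% c("m", "n", "l", "r", "w", "j")) 7L
  else 5L  # stops
}
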