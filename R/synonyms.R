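# Canonical node vocabulary and synonym resolution.
#
# The chondrocyte literature spells the same molecule many ways (NF-kB /
# NF-kappaB, HIF2 / HIF2a, ADAMT4 / ADAMTS4, alpha5beta1 / a5b1 with Greek
# letters). Node lookup is therefore case-insensitive, Greek letters are
# transliterated, punctuation is ignored, and an explicit alias table maps
# the known variant spellings onto one canonical ASCII identifier.
# Names that normalize to nothing known and are not declared in the network
# under scrutiny fail loudly instead of silently creating new nodes.

# normalize a raw node name to a lookup key
normalize_node_key <- function(x) {
  x <- as.character(x)
  # Greek letters and common unicode decorations -> ASCII
  greek <- c("1", "a", "b", "g", "k", "a", "b", "g", "k", "2", "", "1",
             "2", "3", "4", "5")
  names(greek) <- c("\u00df", "\u03b1", "\u03b2", "\u03b3", "\u03ba",
                    "\u0391", "\u0392", "\u0393", "\u039a", "\u00b2",
                    "\u207a", "\u2081", "\u2082", "\u2083", "\u2084",
                    "\u2085")
  greek <- greek[-1]
  for (i in seq_along(greek)) x <- gsub(names(greek)[i], greek[[i]], x, fixed = TRUE)
  x <- tolower(x)
  gsub("[^a-z0-9]", "", x)
}

# canonical id -> category for the packaged vocabulary
.cnet_vocab <- c(
  PIEZO = "mechanosensor", PIEZO1 = "mechanosensor", PIEZO2 = "mechanosensor",
  TRPV4 = "mechanosensor", PTCH = "mechanosensor", Connexin = "mechanosensor",
  TLR = "mechanosensor", CD40 = "other",
  a10b1 = "mechanosensor", a1b1 = "mechanosensor", a2b1 = "mechanosensor",
  a5b1 = "mechanosensor", aVb3 = "mechanosensor", aVb5 = "mechanosensor",
  AP1 = "transcription_factor", CITED2 = "transcription_factor",
  CREB = "transcription_factor", FOXO = "transcription_factor",
  HIF2a = "transcription_factor", NFkB = "transcription_factor",
  Runx2 = "transcription_factor", Sox9 = "transcription_factor",
  bcatenin = "transcription_factor", GLIa = "transcription_factor",
  GLIr = "transcription_factor",
  IL1b = "pro_inflammatory", TNFa = "pro_inflammatory", IL6 = "pro_inflammatory",
  LIF = "pro_inflammatory", IL17 = "pro_inflammatory", IL18 = "pro_inflammatory",
  IL8 = "pro_inflammatory", IFNg = "pro_inflammatory",
  IL10 = "anti_inflammatory", IL13 = "anti_inflammatory",
  IL4 = "anti_inflammatory", IL1Ra = "anti_inflammatory",
  TGFb = "growth_factor", FGF2 = "growth_factor", BMP2 = "growth_factor",
  IGF1 = "growth_factor",
  Agg = "structural_protein", COL2a = "structural_protein",
  FN = "structural_protein", actin = "structural_protein",
  ADAMTS4 = "degrading_enzyme", ADAMTS5 = "degrading_enzyme",
  MMP1 = "degrading_enzyme", MMP3 = "degrading_enzyme",
  MMP13 = "degrading_enzyme", MMP14 = "degrading_enzyme",
  RGD = "other", SP = "second_messenger", Ca2 = "second_messenger",
  ROS = "second_messenger", NO = "second_messenger", ATP = "second_messenger",
  CytochromeC = "second_messenger",
  SMO = "other", SUFU = "other", Ihh = "other", PTHrP = "other",
  Wnt = "other", PGE2 = "other", VEGF = "other"
)

# extra alias spellings (normalized key -> canonical id); the canonical ids'
# own normalized forms are added programmatically below
.cnet_aliases <- c(
  hif2       = "HIF2a",
  adamt4     = "ADAMTS4",
  adamt5     = "ADAMTS5",
  fibronectin = "FN",
  aggrecan   = "Agg",
  col2       = "COL2a",
  col2a1     = "COL2a",
  collagen2  = "COL2a",
  nfkappab   = "NFkB",
  nfkb1      = "NFkB",
  ca         = "Ca2",
  ca2        = "Ca2",
  calcium    = "Ca2",
  betacatenin = "bcatenin",
  catenin    = "bcatenin",
  substancep = "SP",
  alpha5beta1 = "a5b1",
  alphavbeta3 = "aVb3",
  alphavbeta5 = "aVb5",
  alpha1beta1 = "a1b1",
  alpha2beta1 = "a2b1",
  alpha10beta1 = "a10b1",
  il1beta    = "IL1b",
  tnfalpha   = "TNFa",
  tgfbeta    = "TGFb",
  ifngamma   = "IFNg",
  cx43       = "Connexin",
  piezo1     = "PIEZO1",
  piezo2     = "PIEZO2",
  cytc       = "CytochromeC",
  il1ra      = "IL1Ra",
  il1antagonist = "IL1Ra"
)

.cnet_synonym_env <- new.env(parent = emptyenv())

cnet_synonym_table <- function() {
  if (!is.null(.cnet_synonym_env$tab)) return(.cnet_synonym_env$tab)
  tab <- .cnet_aliases
  own <- stats::setNames(names(.cnet_vocab), normalize_node_key(names(.cnet_vocab)))
  # own normalized forms win on clash with an alias
  tab <- c(tab[!(names(tab) %in% names(own))], own)
  .cnet_synonym_env$tab <- tab
  tab
}

#' Canonicalize node identifiers
#'
#' Maps raw node names onto the packaged canonical vocabulary where they are
#' recognized (case-insensitively, with Greek-letter transliteration and
#' punctuation stripped); unknown names are returned unchanged so that user
#' networks can use their own identifiers.
#'
#' @param ids character vector of node names.
#' @return character vector of the same length with canonical identifiers.
#' @examples
#' canonical_node_id(c("NF-kB", "HIF2", "ADAMT4", "myNode"))
#' @export
canonical_node_id <- function(ids) {
  tab <- cnet_synonym_table()
  keys <- normalize_node_key(ids)
  hit <- keys %in% names(tab)
  out <- as.character(ids)
  out[hit] <- unname(tab[keys[hit]])
  out
}

# category guess for a canonical id ("other" if unknown)
canonical_node_category <- function(ids) {
  cat <- unname(.cnet_vocab[ids])
  cat[is.na(cat)] <- "other"
  cat
}

#' Resolve node names against a network
#'
#' Case-insensitive, synonym-aware lookup of node names in an interactome.
#' Unresolvable names raise an error naming them (they are never silently
#' added as new nodes).
#'
#' @param net an [interactome()].
#' @param ids character vector of node names to resolve.
#' @return character vector of matching canonical node ids in `net`.
#' @export
resolve_nodes <- function(net, ids) {
  stopifnot(inherits(net, "interactome"))
  keys <- normalize_node_key(canonical_node_id(ids))
  net_keys <- normalize_node_key(net$nodes$id)
  idx <- match(keys, net_keys)
  if (anyNA(idx)) {
    stop_cnet("unknown node(s) in network '", net$name, "': ",
              paste(ids[is.na(idx)], collapse = ", "),
              class = "cnet_lookup_error")
  }
  net$nodes$id[idx]
}

node_categories <- function() {
  c("mechanosensor", "transcription_factor", "pro_inflammatory",
    "anti_inflammatory", "growth_factor", "structural_protein",
    "degrading_enzyme", "second_messenger", "other")
}
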