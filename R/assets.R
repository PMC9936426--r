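# Packaged network assets.

cnet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "chondronet")
  if (path == "")
    stop_cnet("packaged asset not found: ", file, class = "cnet_io_error")
  path
}

#' Load the curated 118-node chondrocyte interactome
#'
#' The full curated network (118 nodes, 358 signed directed edges) exists
#' only as a supplementary table of the source publication and has not been
#' transcribed into this package. Calling this function therefore raises an
#' explicit "curated asset unavailable" error; use [load_reduced_network()]
#' for the packaged figure-derived subnetwork, which supports every module
#' of the package.
#'
#' @return never returns; raises an error of class
#'   `cnet_curated_unavailable`.
#' @export
load_curated_network <- function() {
  path <- system.file("extdata", "curated_chondrocyte.csv",
                      package = "chondronet")
  if (path != "")
    return(parse_network(path, format = "edge_csv", name = "curated"))
  stop_cnet("curated asset unavailable: the 118-node / 358-edge table is ",
            "published only in supplementary material and is not shipped ",
            "with this package; use load_reduced_network() instead",
            class = "cnet_curated_unavailable")
}

#' Load the reduced figure-derived chondrocyte network
#'
#' A ~50-node subnetwork of the chondrocyte mechano-inflammatory interactome
#' assembled strictly from pathway statements (integrin alpha5beta1 ->
#' substance P -> IL-4 axis, TRPV4/PIEZO calcium signalling, the
#' fibronectin-integrin-actin module with its RGD conformational switch,
#' the NF-kB inflammatory core with cytokine feedback, Wnt/beta-catenin and
#' TLR inputs, hedgehog and PTHrP routes, and matrix-degrading enzymes that
#' release RGD fragments). It is a synthetic stand-in for the full curated
#' network and carries the same two RGD switch rules at threshold 0.5.
#'
#' @return a validated [interactome()] named `"reduced_chondrocyte"`.
#' @export
load_reduced_network <- function() {
  parse_network(cnet_extdata("reduced_chondrocyte.csv"), format = "edge_csv",
                name = "reduced_chondrocyte")
}

# resolve a --network argument: builtin name, motif:<name>, or a file path
resolve_network_arg <- function(spec, format = "edge_csv") {
  if (spec == "curated") return(load_curated_network())
  if (spec == "reduced") return(load_reduced_network())
  if (startsWith(spec, "motif:")) return(make_motif(sub("^motif:", "", spec)))
  fmt <- if (grepl("\\.sif$", spec)) "sif" else format
  parse_network(spec, format = fmt)
}
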