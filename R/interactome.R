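# Signed directed regulatory networks: construction, validation, I/O.

#' Construct a signed directed interactome
#'
#' The central container of the package: a set of nodes (each with a sigmoid
#' gain `h` and a decay rate `gamma`), signed weighted directed edges
#' (activating or inhibiting), and optional state-dependent switch rules
#' (see [switch_rule()]). Node identifiers are canonicalized against the
#' packaged synonym table ([canonical_node_id()]); nodes referenced only by
#' edges are added with default metadata.
#'
#' @param nodes data.frame with columns `id` and optionally `category`, `h`
#'   (default 10), `gamma` (default 1); or a character vector of ids.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activates"`/`"inhibits"`, aliases `+1`/`-1` accepted) and optionally
#'   `weight` (default 1).
#' @param switch_rules list of [switch_rule()] objects.
#' @param name network name used in messages and provenance headers.
#' @param allow_contradictory if `TRUE`, permit the same (source, target)
#'   pair to carry both an activating and an inhibiting edge; both then
#'   enter the normalized input on their respective sides. Off by default.
#' @return an object of class `"interactome"`.
#' @seealso [parse_network()], [partition_inputs()], [load_reduced_network()]
#' @export
interactome <- function(nodes = NULL, edges = NULL, switch_rules = list(),
                        name = "network", allow_contradictory = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop_cnet("edges need columns source, target, sign",
              class = "cnet_validation_error")
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$weight[is.na(edges$weight)] <- 1
  edges$sign <- normalize_sign(edges$sign)
  edges$source <- canonical_node_id(edges$source)
  edges$target <- canonical_node_id(edges$target)

  if (is.null(nodes)) nodes <- character()
  if (is.character(nodes)) nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) > 0 && !"id" %in% names(nodes))
    stop_cnet("node table needs an 'id' column", class = "cnet_validation_error")
  if (nrow(nodes) == 0) nodes <- data.frame(id = character(), stringsAsFactors = FALSE)
  nodes$id <- canonical_node_id(nodes$id)

  # nodes appearing only in edges get default metadata
  extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(extra) > 0) {
    nodes <- merge_node_defaults(nodes)
    nodes <- rbind(nodes, data.frame(
      id = extra, category = canonical_node_category(extra),
      h = 10, gamma = 1, stringsAsFactors = FALSE))
  } else {
    nodes <- merge_node_defaults(nodes)
  }

  net <- structure(list(nodes = nodes, edges = edges,
                        switch_rules = switch_rules, name = name,
                        allow_contradictory = isTRUE(allow_contradictory)),
                   class = "interactome")
  validate_interactome(net)
  net
}

merge_node_defaults <- function(nodes) {
  n <- nrow(nodes)
  if (is.null(nodes$category)) nodes$category <- canonical_node_category(nodes$id)
  nodes$category[is.na(nodes$category) | nodes$category == ""] <- "other"
  if (is.null(nodes$h)) nodes$h <- rep(10, n)
  if (is.null(nodes$gamma)) nodes$gamma <- rep(1, n)
  nodes$h[is.na(nodes$h)] <- 10
  nodes$gamma[is.na(nodes$gamma)] <- 1
  nodes[, c("id", "category", "h", "gamma")]
}

normalize_sign <- function(sign) {
  s <- trimws(tolower(as.character(sign)))
  map <- c(activates = "activates", activate = "activates", activation = "activates",
           "+1" = "activates", "1" = "activates", "+" = "activates",
           inhibits = "inhibits", inhibit = "inhibits", inhibition = "inhibits",
           "-1" = "inhibits", "-" = "inhibits")
  out <- map[s]
  if (anyNA(out))
    stop_cnet("unknown edge sign token(s): ",
              paste(unique(s[is.na(out)]), collapse = ", "),
              class = "cnet_parse_error")
  unname(out)
}

#' Declare a state-dependent topology switch
#'
#' A switch rule watches one node; whenever that node's activation is
#' strictly above `threshold` the listed edge modifications are applied to
#' the base topology (they are reverted as soon as the activation falls back
#' to or below the threshold -- the switch has no hysteresis). This encodes
#' conformational changes such as the RGD-driven integrin switch, where
#' ligand identity flips an edge from activating to inhibiting.
#'
#' @param watch node id whose activation is monitored.
#' @param threshold switching threshold in (0, 1); the paper's integrin
#'   switch uses 0.5.
#' @param when_above list of modifications, each created by one of
#'   `flip_sign(source, target)`, `remove_edge(source, target)`,
#'   `add_edge(source, target, sign, weight = 1)`.
#' @return an object of class `"switch_rule"`.
#' @export
switch_rule <- function(watch, threshold = 0.5, when_above = list()) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  structure(list(watch = canonical_node_id(watch), threshold = threshold,
                 when_above = when_above),
            class = "switch_rule")
}

#' @rdname switch_rule
#' @param source,target edge endpoints.
#' @export
flip_sign <- function(source, target) {
  list(op = "flip_sign", source = canonical_node_id(source),
       target = canonical_node_id(target))
}

#' @rdname switch_rule
#' @export
remove_edge <- function(source, target) {
  list(op = "remove_edge", source = canonical_node_id(source),
       target = canonical_node_id(target))
}

#' @rdname switch_rule
#' @param sign `"activates"` or `"inhibits"` for the added edge.
#' @param weight positive weight for the added edge.
#' @export
add_edge <- function(source, target, sign, weight = 1) {
  list(op = "add_edge", source = canonical_node_id(source),
       target = canonical_node_id(target), sign = normalize_sign(sign),
       weight = weight)
}

#' Validate an interactome
#'
#' Checks all structural invariants: unique canonical node ids, positive
#' `h`, `gamma` and edge weights, no dangling edges, no duplicate edges (a
#' contradictory activating + inhibiting pair is rejected unless the network
#' was built with `allow_contradictory = TRUE`), and switch rules whose
#' referenced nodes and edges exist in the base topology.
#'
#' @param net an [interactome()].
#' @return `net`, invisibly; errors of class `cnet_validation_error` otherwise.
#' @export
validate_interactome <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (nrow(nodes) < 1)
    stop_cnet("network must contain at least one node",
              class = "cnet_validation_error")
  dup <- duplicated(normalize_node_key(nodes$id))
  if (any(dup))
    stop_cnet("duplicate node id(s) after canonicalization: ",
              paste(unique(nodes$id[dup]), collapse = ", "),
              class = "cnet_validation_error")
  if (any(nodes$h <= 0) || any(nodes$gamma <= 0))
    stop_cnet("node h and gamma must be > 0", class = "cnet_validation_error")
  if (nrow(edges) > 0) {
    if (any(edges$weight <= 0))
      stop_cnet("edge weights must be > 0", class = "cnet_validation_error")
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(missing) > 0)
      stop_cnet("dangling edge endpoint(s): ", paste(missing, collapse = ", "),
                class = "cnet_validation_error")
    key <- paste(edges$source, edges$target, edges$sign)
    if (anyDuplicated(key))
      stop_cnet("duplicate edge(s): ",
                paste(unique(key[duplicated(key)]), collapse = "; "),
                class = "cnet_validation_error")
    pkey <- paste(edges$source, edges$target)
    if (!net$allow_contradictory && anyDuplicated(pkey))
      stop_cnet("contradictory duplicate edge(s) (both signs) for: ",
                paste(unique(pkey[duplicated(pkey)]), collapse = "; "),
                "; pass allow_contradictory = TRUE to permit",
                class = "cnet_validation_error")
  }
  for (rule in net$switch_rules) {
    if (!inherits(rule, "switch_rule"))
      stop_cnet("switch_rules must be switch_rule objects",
                class = "cnet_validation_error")
    if (!rule$watch %in% nodes$id)
      stop_cnet("switch rule watches unknown node: ", rule$watch,
                class = "cnet_validation_error")
    for (mod in rule$when_above) {
      if (!all(c(mod$source, mod$target) %in% nodes$id))
        stop_cnet("switch rule references unknown node(s): ",
                  mod$source, " > ", mod$target,
                  class = "cnet_validation_error")
      present <- any(edges$source == mod$source & edges$target == mod$target)
      if (mod$op %in% c("flip_sign", "remove_edge") && !present)
        stop_cnet("switch rule ", mod$op, " references missing base edge ",
                  mod$source, " > ", mod$target,
                  class = "cnet_validation_error")
      if (mod$op == "add_edge" && present)
        stop_cnet("switch rule add_edge duplicates base edge ",
                  mod$source, " > ", mod$target,
                  class = "cnet_validation_error")
    }
  }
  invisible(net)
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", x$name, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", length(x$switch_rules), " switch rule(s)\n",
      sep = "")
  invisible(x)
}

#' @export
format.interactome <- function(x, ...) {
  sprintf("<interactome> %s: %d nodes, %d edges", x$name, nrow(x$nodes),
          nrow(x$edges))
}

#' Number of nodes of an interactome
#' @param net an [interactome()].
#' @return integer node count (the model's N).
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' Partition a node's inputs into activators and inhibitors
#'
#' Every incoming edge of a node belongs to exactly one of the two sets that
#' drive the normalized input: the activators (weights `alpha`) or the
#' inhibitors (weights `beta`). Both lists are ordered lexicographically by
#' source id, so the partition is deterministic.
#'
#' @param net an [interactome()].
#' @param node a node name (synonyms accepted).
#' @return list with data.frames `activators` and `inhibitors`, each with
#'   columns `source` and `weight`.
#' @export
partition_inputs <- function(net, node) {
  id <- resolve_nodes(net, node)
  incoming <- net$edges[net$edges$target == id, , drop = FALSE]
  out <- lapply(c(activates = "activates", inhibits = "inhibits"), function(s) {
    sub <- incoming[incoming$sign == s, c("source", "weight"), drop = FALSE]
    sub <- sub[order(sub$source), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  list(activators = out$activates, inhibitors = out$inhibits)
}

# ---- file I/O ------------------------------------------------------------

#' Read a network from disk
#'
#' Two plain-text dialects are supported. `edge_csv`: UTF-8 CSV with header
#' `source,target,sign,weight` (sign tokens `activates`/`inhibits`, aliases
#' `+1`/`-1`); an optional companion node file (`<stem>.nodes.csv`, header
#' `node,category,h,gamma`) and switch-rule file (`<stem>.rules.json`) are
#' merged automatically when present. `sif`: tab-separated
#' `source<TAB>activates|inhibits<TAB>target` with all weights 1.
#'
#' @param path path of the edge file.
#' @param format `"edge_csv"` or `"sif"`.
#' @param nodes_path,rules_path explicit companion file paths (otherwise
#'   derived from `path`).
#' @param name network name (defaults to the file stem).
#' @param allow_contradictory see [interactome()].
#' @return a validated [interactome()].
#' @export
parse_network <- function(path, format = c("edge_csv", "sif"),
                          nodes_path = NULL, rules_path = NULL,
                          name = NULL, allow_contradictory = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_cnet("network file not found: ", path, class = "cnet_io_error")
  stem <- sub("\\.(csv|sif|tsv|txt)$", "", path)
  nodes_path <- nodes_path %||% paste0(stem, ".nodes.csv")
  rules_path <- rules_path %||% paste0(stem, ".rules.json")
  name <- name %||% basename(stem)

  edges <- if (format == "edge_csv") parse_edge_csv(path) else parse_sif(path)
  nodes <- NULL
  if (file.exists(nodes_path)) {
    nd <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
    if (!"node" %in% names(nd))
      stop_cnet("node file needs a 'node' column: ", nodes_path,
                class = "cnet_parse_error")
    names(nd)[names(nd) == "node"] <- "id"
    nodes <- nd
  }
  rules <- list()
  if (file.exists(rules_path)) rules <- read_switch_rules(rules_path)
  interactome(nodes = nodes, edges = edges, switch_rules = rules,
              name = name, allow_contradictory = allow_contradictory)
}

parse_edge_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0 || !nzchar(trimws(lines[1])))
    return(data.frame(source = character(), target = character(),
                      sign = character(), weight = numeric()))
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!all(c("source", "target", "sign") %in% header))
    stop_cnet("edge_csv header must contain source,target,sign (line 1)",
              class = "cnet_parse_error")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0)
    return(data.frame(source = character(), target = character(),
                      sign = character(), weight = numeric()))
  parts <- strsplit(body, ",")
  nf <- lengths(parts)
  bad <- which(nf < 3 | nf > length(header))
  if (length(bad) > 0)
    stop_cnet("malformed edge_csv row at line ", bad[1] + 1, ": ", body[bad[1]],
              class = "cnet_parse_error")
  get <- function(col, default = NA_character_) {
    j <- match(col, header)
    if (is.na(j)) return(rep(default, length(parts)))
    vapply(parts, function(p) if (length(p) >= j) trimws(p[j]) else default,
           character(1))
  }
  w <- suppressWarnings(as.numeric(get("weight", "1")))
  w[is.na(w)] <- 1
  data.frame(source = get("source"), target = get("target"),
             sign = get("sign"), weight = w, stringsAsFactors = FALSE)
}

parse_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(source = character(), target = character(),
                      sign = character(), weight = numeric()))
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop_cnet("malformed SIF row at line ", bad[1], ": ", lines[bad[1]],
              class = "cnet_parse_error")
  m <- do.call(rbind, parts)
  data.frame(source = trimws(m[, 1]), target = trimws(m[, 3]),
             sign = trimws(m[, 2]), weight = 1, stringsAsFactors = FALSE)
}

#' Write a network to disk
#'
#' Serializes an interactome so that [parse_network()] reproduces it exactly
#' (node set, edge multiset, switch rules). The SIF dialect carries no
#' weights; serializing a weighted network to SIF is refused as a documented
#' lossy case. Node metadata goes to `<stem>.nodes.csv`, switch rules to
#' `<stem>.rules.json`.
#'
#' @param net an [interactome()].
#' @param path output path for the edge file.
#' @param format `"edge_csv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
serialize_network <- function(net, path, format = c("edge_csv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "interactome"))
  stem <- sub("\\.(csv|sif|tsv|txt)$", "", path)
  edges <- net$edges[order(net$edges$source, net$edges$target, net$edges$sign),
                     , drop = FALSE]
  if (format == "edge_csv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines("source,target,sign,weight", con)
    if (nrow(edges) > 0)
      writeLines(paste(edges$source, edges$target, edges$sign,
                       format(edges$weight, digits = 15, scientific = FALSE,
                              trim = TRUE), sep = ","), con)
    close(con)
  } else {
    if (any(edges$weight != 1))
      stop_cnet("SIF cannot carry weights != 1 (lossy serialization refused)",
                class = "cnet_io_error")
    writeLines(paste(edges$source, edges$sign, edges$target, sep = "\t"),
               file.path(path))
  }
  nd <- net$nodes[order(net$nodes$id), , drop = FALSE]
  names(nd)[names(nd) == "id"] <- "node"
  utils::write.csv(nd, paste0(stem, ".nodes.csv"), row.names = FALSE,
                   quote = FALSE)
  if (length(net$switch_rules) > 0)
    write_switch_rules(net$switch_rules, paste0(stem, ".rules.json"))
  invisible(path)
}

# switch rules <-> JSON config block:
#   [{"watch": "RGD", "threshold": 0.5,
#     "when_above": ["flip_sign: a5b1>actin", "remove_edge: FN>a5b1",
#                    "add_edge: RGD>a5b1:activates"]}]
write_switch_rules <- function(rules, path) {
  enc <- lapply(rules, function(r) {
    mods <- vapply(r$when_above, function(m) {
      switch(m$op,
             flip_sign   = sprintf("flip_sign: %s>%s", m$source, m$target),
             remove_edge = sprintf("remove_edge: %s>%s", m$source, m$target),
             add_edge    = sprintf("add_edge: %s>%s:%s", m$source, m$target,
                                   m$sign))
    }, character(1))
    list(watch = r$watch, threshold = r$threshold, when_above = mods)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

read_switch_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    mods <- lapply(r$when_above, parse_rule_mod)
    switch_rule(watch = r$watch, threshold = r$threshold, when_above = mods)
  })
}

parse_rule_mod <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^(flip_sign|remove_edge|add_edge)\\s*:\\s*([^>]+)>([^:]+)(:(.+))?$", s))[[1]]
  if (length(m) == 0)
    stop_cnet("malformed switch-rule modification: ", s,
              class = "cnet_parse_error")
  op <- m[2]; src <- trimws(m[3]); tgt <- trimws(m[4])
  if (op == "add_edge") {
    if (!nzchar(m[6]))
      stop_cnet("add_edge needs a sign: ", s, class = "cnet_parse_error")
    add_edge(src, tgt, trimws(m[6]))
  } else if (op == "flip_sign") flip_sign(src, tgt) else remove_edge(src, tgt)
}

# canonical sortable edge representation, used by round-trip tests
edge_signature <- function(net) {
  e <- net$edges
  sig <- sprintf("%s|%s|%s|%.12g", e$source, e$target, e$sign, e$weight)
  sort(sig)
}
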