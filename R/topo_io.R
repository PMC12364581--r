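# Reading and writing the tab-separated ".topo" topology format
# (Source <TAB> Target <TAB> Type; Type 1 = activation, 2 = inhibition).
# The format carries signs only; real-valued edge weights travel in a JSON
# sidecar (see write_weights / apply_weights) so the .topo file itself stays
# interchange-compatible.

#' Read a signed network topology from a .topo file
#'
#' The .topo dialect is tab-separated with header `Source  Target  Type` and
#' one row per edge; `Type` 1 is an activation, 2 an inhibition. A missing
#' header row is tolerated with a warning. Node order is the order of first
#' appearance in the file; all roles default to `"core"`.
#'
#' @param path path to a .topo file
#' @param weights optional path to a JSON weight sidecar (see
#'   [write_weights()]) applied to the signed adjacency.
#' @return a [signed_network()] whose adjacency has `+1` at (source, target)
#'   for activations and `-1` for inhibitions.
#' @examples
#' f <- tempfile(fileext = ".topo")
#' write_topo(make_toggle(2), f)
#' read_topo(f)
#' @export
read_topo <- function(path, weights = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop("topology file '", path, "' is empty (no nodes)")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  has_header <- length(first) >= 3 && first[1] == "source" &&
    first[2] == "target" && first[3] == "type"
  if (!has_header) {
    warning("no 'Source\\tTarget\\tType' header in '", path,
            "'; assuming all rows are edges")
    body <- seq_along(lines)
  } else {
    body <- seq_along(lines)[-1]
  }
  if (length(body) == 0)
    stop("topology file '", path, "' declares a header but no edges (no nodes)")

  nodes <- character(0)
  edges <- list()
  seen <- character(0)
  for (ln in body) {
    f <- trimws(fields[[ln]])
    if (length(f) != 3)
      stop("malformed row at line ", ln, " of '", path,
           "': expected 3 tab-separated fields")
    type <- suppressWarnings(as.integer(f[3]))
    if (is.na(type) || !type %in% c(1L, 2L))
      stop("unknown Type '", f[3], "' at line ", ln, " of '", path,
           "' (must be 1 = activation or 2 = inhibition)")
    key <- paste0(f[1], "\r", f[2])
    if (key %in% seen)
      stop("duplicate edge ", f[1], " -> ", f[2], " at line ", ln,
           " of '", path, "'")
    seen <- c(seen, key)
    for (nd in f[1:2]) if (!nd %in% nodes) nodes <- c(nodes, nd)
    edges[[length(edges) + 1L]] <- list(src = f[1], tgt = f[2], type = type)
  }
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in edges)
    adj[e$src, e$tgt] <- if (e$type == 1L) 1 else -1
  net <- signed_network(adj)
  if (!is.null(weights)) net <- apply_weights(net, weights)
  net
}

#' Write a signed network to a .topo file
#'
#' Only sign-valued networks (all adjacency entries in `-1, 0, +1`) can be
#' serialized; real-valued weights must go to the JSON sidecar via
#' [write_weights()]. Edges are written grouped by regulator in node order so
#' that [read_topo()] reproduces the node order of complete networks.
#'
#' @param network a [signed_network()] with sign-valued adjacency
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_topo <- function(network, path) {
  adj <- network$adjacency
  if (!all(adj %in% c(-1, 0, 1)))
    stop("adjacency carries real-valued weights; .topo stores signs only -- ",
         "serialize weights with write_weights() and pass the sidecar to ",
         "read_topo()")
  idx <- which(t(adj) != 0, arr.ind = TRUE) # t(): rows grouped by regulator
  if (nrow(idx) == 0)
    stop("network has no edges; refusing to write an empty .topo file")
  src <- network$nodes[idx[, "col"]]
  tgt <- network$nodes[idx[, "row"]]
  type <- ifelse(adj[cbind(idx[, "col"], idx[, "row"])] > 0, 1L, 2L)
  orphan <- setdiff(network$nodes, c(src, tgt))
  if (length(orphan))
    warning("isolated node(s) ", paste(orphan, collapse = ", "),
            " cannot be represented in the edge-list format and are dropped")
  df <- data.frame(Source = src, Target = tgt, Type = type)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the real-valued edge weights of a network to a JSON sidecar
#'
#' The sidecar is a JSON map `{"A->B": weight}` holding the signed weight of
#' every edge whose magnitude differs from 1; absent keys mean magnitude 1.
#'
#' @param network a [signed_network()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_weights <- function(network, path) {
  adj <- network$adjacency
  idx <- which(adj != 0 & abs(adj) != 1, arr.ind = TRUE)
  w <- list()
  if (nrow(idx) > 0) {
    keys <- paste0(network$nodes[idx[, 1]], "->", network$nodes[idx[, 2]])
    w <- as.list(setNames(adj[idx], keys))
  }
  jsonlite::write_json(w, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a JSON weight sidecar to a signed network
#'
#' @param network a [signed_network()] with sign-valued adjacency
#' @param path path to a sidecar written by [write_weights()]
#' @return the network with the listed edges re-weighted; the sign of every
#'   sidecar weight must agree with the sign in the topology.
#' @export
apply_weights <- function(network, path) {
  w <- jsonlite::read_json(path)
  for (key in names(w)) {
    parts <- strsplit(key, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed weight key '", key, "' (expected 'source->target')")
    i <- .node_index(network, parts[1])
    j <- .node_index(network, parts[2])
    val <- as.numeric(w[[key]])
    cur <- network$adjacency[i, j]
    if (cur == 0)
      stop("weight given for absent edge ", key)
    if (sign(val) != sign(cur))
      stop("sidecar weight for ", key, " has sign ", sign(val),
           " but the topology says ", sign(cur))
    network$adjacency[i, j] <- val
  }
  network
}
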