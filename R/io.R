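#' Read a network from extended Newick
#'
#' Parses an extended Newick string (or file containing one) into a
#' [rooted_network()]. Hybrid (reticulation) nodes carry `#H<k>` tags and
#' appear exactly twice: once with their subtree and once as a tag-only
#' reference, per the common eNewick convention. Plain Newick is accepted
#' for trees. Branch lengths and internal node labels are parsed and
#' discarded with a warning. If the outermost node has two children (plain
#' Newick), an explicit outdegree-1 root is added above it.
#'
#' @param text an eNewick string, or a path to a file whose first
#'   non-empty line holds one.
#' @param resolve if `TRUE`, multifurcations are resolved arbitrarily
#'   (left comb); otherwise non-binary input is an error.
#' @return a `rooted_network`.
#' @export
read_enewick <- function(text, resolve = FALSE) {
  if (length(text) == 1 && !grepl("[();]", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
    text <- text[nzchar(trimws(text))][1]
  }
  text <- trimws(paste(text, collapse = ""))
  if (!endsWith(text, ";")) stop("parse error at position ", nchar(text),
                                 ": expected ';'")
  src <- substr(text, 1, nchar(text) - 1)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$src <- src
  st$arcs <- matrix(character(0), ncol = 2)
  st$labels <- character(0)
  st$hybrids <- list()  # tag -> node id
  st$counter <- 0L
  st$dropped <- FALSE
  top <- parse_subtree(st, resolve)
  if (st$pos <= nchar(src)) {
    stop("parse error at position ", st$pos, ": trailing input")
  }
  if (st$dropped) {
    warning("branch lengths / internal labels were discarded")
  }
  # ensure explicit outdegree-1 root
  nchild <- sum(st$arcs[, 1] == top$id)
  if (nchild != 1) {
    rho <- new_parse_node(st)
    st$arcs <- rbind(st$arcs, c(rho, top$id))
  }
  rooted_network(st$arcs, st$labels)
}

new_parse_node <- function(st) {
  st$counter <- st$counter + 1L
  paste0("v", st$counter)
}

peek <- function(st) {
  if (st$pos > nchar(st$src)) "" else substr(st$src, st$pos, st$pos)
}

parse_subtree <- function(st, resolve) {
  if (peek(st) == "(") {
    st$pos <- st$pos + 1L
    kids <- list(parse_subtree(st, resolve))
    while (peek(st) == ",") {
      st$pos <- st$pos + 1L
      kids <- c(kids, list(parse_subtree(st, resolve)))
    }
    if (peek(st) != ")") stop("parse error at position ", st$pos,
                              ": expected ')'")
    st$pos <- st$pos + 1L
    ann <- parse_annotation(st)
    if (length(kids) > 2) {
      if (!resolve) stop("non-binary input (", length(kids),
                         " children); set resolve = TRUE to resolve")
      while (length(kids) > 2) {
        comb <- new_parse_node(st)
        st$arcs <- rbind(st$arcs,
                         c(comb, kids[[1]]$id), c(comb, kids[[2]]$id))
        kids <- c(list(list(id = comb)), kids[-(1:2)])
      }
    }
    if (!is.null(ann$hybrid)) {
      id <- hybrid_node(st, ann$hybrid)
    } else {
      id <- new_parse_node(st)
    }
    if (nzchar(ann$name)) st$dropped <- TRUE  # internal label discarded
    for (k in kids) st$arcs <- rbind(st$arcs, c(id, k$id))
    list(id = id)
  } else {
    ann <- parse_annotation(st)
    if (!nzchar(ann$name) && is.null(ann$hybrid)) {
      stop("parse error at position ", st$pos, ": expected a node")
    }
    if (!is.null(ann$hybrid)) {
      id <- hybrid_node(st, ann$hybrid)
      if (nzchar(ann$name)) st$dropped <- TRUE
    } else {
      id <- new_parse_node(st)
      st$labels[id] <- ann$name
      names(st$labels)[length(st$labels)] <- id
    }
    list(id = id)
  }
}

hybrid_node <- function(st, tag) {
  if (is.null(st$hybrids[[tag]])) {
    st$hybrids[[tag]] <- new_parse_node(st)
  }
  st$hybrids[[tag]]
}

parse_annotation <- function(st) {
  m <- regexpr("^[^(),:;#]*", substr(st$src, st$pos, nchar(st$src)))
  name <- regmatches(substr(st$src, st$pos, nchar(st$src)), m)
  st$pos <- st$pos + nchar(name)
  hybrid <- NULL
  if (peek(st) == "#") {
    st$pos <- st$pos + 1L
    m2 <- regexpr("^[A-Za-z]*[0-9]+", substr(st$src, st$pos, nchar(st$src)))
    if (m2 == -1) stop("parse error at position ", st$pos,
                       ": malformed hybrid tag")
    hybrid <- regmatches(substr(st$src, st$pos, nchar(st$src)), m2)
    st$pos <- st$pos + nchar(hybrid)
  }
  if (peek(st) == ":") {
    st$pos <- st$pos + 1L
    m3 <- regexpr("^[0-9.eE+-]+", substr(st$src, st$pos, nchar(st$src)))
    if (m3 == -1) stop("parse error at position ", st$pos,
                       ": malformed branch length")
    st$pos <- st$pos + nchar(regmatches(substr(st$src, st$pos, nchar(st$src)), m3))
    st$dropped <- TRUE
  }
  list(name = trimws(name), hybrid = hybrid)
}

#' Write a network as extended Newick
#'
#' Inverse of [read_enewick()]: emits the network with its outdegree-1 root
#' as the outermost unary wrapper and each reticulation tagged `#H<k>`. The
#' subtree of a reticulation is printed at its canonically-least parent;
#' other parents print a tag-only reference. `read_enewick(write_enewick(n))`
#' is isomorphic to `n`.
#'
#' @param net a valid `rooted_network`.
#' @return an eNewick string ending in `;`.
#' @export
write_enewick <- function(net) {
  rho <- net_root(net)
  retics <- net_reticulations(net)
  tags <- stats::setNames(paste0("H", seq_along(retics)), retics)
  expanded <- stats::setNames(logical(length(retics)), retics)
  env <- environment()
  emit <- function(v) {
    lab <- if (v %in% names(net$labels)) net$labels[[v]] else ""
    if (v %in% retics) {
      if (env$expanded[[v]]) return(paste0(lab, "#", tags[[v]]))
      env$expanded[[v]] <- TRUE
      kids <- sort_nodes(net_children(net, v))
      return(paste0("(", paste(vapply(kids, emit, character(1)),
                               collapse = ","), ")", lab, "#", tags[[v]]))
    }
    kids <- sort_nodes(net_children(net, v))
    if (length(kids) == 0) return(lab)
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")",
           lab)
  }
  paste0("(", emit(net_children(net, rho)[[1]]), ");")
}

#' JSON round trip for rooted networks
#'
#' `write_net_json` serialises a network as
#' `{"nodes": [...], "arcs": [[u,v], ...], "labels": {node: taxon}}`;
#' `read_net_json` restores it bit-exactly (same node ids).
#'
#' @param net a `rooted_network`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @param text JSON string or file path.
#' @return `write_net_json`: the JSON string (invisibly if written to file).
#'   `read_net_json`: a `rooted_network`.
#' @export
write_net_json <- function(net, path = NULL) {
  obj <- list(
    nodes = net$nodes,
    arcs = unname(apply(net$arcs, 1, function(r) as.list(r), simplify = FALSE)),
    labels = as.list(net$labels)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname write_net_json
#' @export
read_net_json <- function(text) {
  if (length(text) == 1 && !grepl("[{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  arcs <- do.call(rbind, lapply(obj$arcs, function(a) c(a[[1]], a[[2]])))
  labels <- unlist(obj$labels)
  net <- rooted_network(arcs, labels)
  stopifnot(setequal(net$nodes, unlist(obj$nodes)))
  net
}
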