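#' @useDynLib netcontagion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median model.matrix plogis qlogis quantile rbinom rnorm runif sd setNames aggregate as.formula density rgamma rpois cov dnorm
#' @importFrom utils read.csv write.csv head
NULL

# Name-generator labels.  chatting/respect are single-sampled; borrow_* and
# advice_* are the two sides of the double-sampled money and advice networks.
GENERATORS <- c("chatting", "respect", "borrow_out", "borrow_in",
                "advice_out", "advice_in")

# Generators whose reports describe the reverse relation: "who would come to
# you" means the named alter is the seeker, so the stored tie runs alter -> ego.
REVERSED_GENERATORS <- c("borrow_in", "advice_in")

UNMATCHED <- "UNMATCHED"

#' Construct a directed network over a fixed roster
#'
#' A `directed_network` is the container used throughout the package for one
#' layer of a socio-centric network: an ordered roster of respondent ids plus
#' a set of directed ties, each optionally flagged as kin.  Row order of the
#' roster defines the index order of every attribute vector used downstream.
#'
#' @param roster character vector of unique respondent ids.
#' @param from,to tie endpoints, as ids (character) or 1-based roster indices.
#' @param kin logical vector flagging kin ties (recycled).
#' @param layer label for the layer (e.g. `"chatting"`).
#' @return An object of class `directed_network` with elements `roster`,
#'   `from`, `to` (integer indices into the roster), `kin` and `layer`.
#'   Self-ties are forbidden and duplicate ordered pairs are collapsed (a
#'   pair is kin if any duplicate was kin).
#' @export
directed_network <- function(roster, from = integer(), to = integer(),
                             kin = FALSE, layer = "network") {
  roster <- as.character(roster)
  if (anyDuplicated(roster)) {
    stop("duplicate id in roster: ", roster[duplicated(roster)][1L])
  }
  if (is.character(from)) from <- match(from, roster)
  if (is.character(to)) to <- match(to, roster)
  from <- as.integer(from)
  to <- as.integer(to)
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  if (anyNA(from) || anyNA(to)) stop("tie endpoint not found in roster")
  if (length(from) &&
      (min(from, to) < 1L || max(from, to) > length(roster))) {
    stop("tie endpoint index outside roster")
  }
  if (any(from == to)) stop("self-ties are not allowed")
  kin <- rep_len(as.logical(kin), length(from))
  kin[is.na(kin)] <- FALSE
  if (length(from)) {
    key <- paste(from, to)
    if (anyDuplicated(key)) {
      kin <- as.logical(tapply(kin, key, any)[unique(key)])
      keep <- !duplicated(key)
      from <- from[keep]
      to <- to[keep]
    }
  }
  structure(list(roster = roster, from = from, to = to, kin = kin,
                 layer = layer),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network '%s': %d nodes, %d ties (%d kin)>\n",
              x$layer, length(x$roster), length(x$from), sum(x$kin)))
  invisible(x)
}

n_nodes <- function(net) length(net$roster)
n_ties <- function(net) length(net$from)

#' Dense adjacency matrix of a directed network
#'
#' @param net a [directed_network()].
#' @param kin_only,nonkin_only restrict to kin or non-kin ties.
#' @return 0/1 integer matrix with roster ids as dimnames.
#' @export
adjacency_matrix <- function(net, kin_only = FALSE, nonkin_only = FALSE) {
  n <- n_nodes(net)
  A <- matrix(0L, n, n, dimnames = list(net$roster, net$roster))
  keep <- rep(TRUE, n_ties(net))
  if (kin_only) keep <- net$kin
  if (nonkin_only) keep <- !net$kin
  A[cbind(net$from[keep], net$to[keep])] <- 1L
  A
}

#' Build one network layer from nomination records
#'
#' Converts the nomination table for one name generator into a directed
#' network over the roster.  Matched nominations become ties; alters marked
#' `UNMATCHED` (or absent from the roster) are dropped and counted.  For the
#' "in"-direction generators (`borrow_in`, `advice_in`) the reported pair is
#' reversed, so that both sides of a double-sampled pair describe the same
#' directed relation (the tie always points from the seeker of the
#' relationship to its provider).
#'
#' @param nominations data frame with columns `ego`, `generator`, `alter`,
#'   `kin` (and optionally `relationship`).
#' @param generator one of `r paste(GENERATORS, collapse = ", ")`.
#' @param roster character vector of respondent ids defining the node set.
#' @return A [directed_network()]; attribute `"n_unmatched"` carries the
#'   number of dropped nominations.
#' @export
build_layer <- function(nominations, generator, roster) {
  if (!generator %in% GENERATORS) {
    stop("unknown generator label: ", generator)
  }
  nm <- nominations[nominations$generator == generator, , drop = FALSE]
  roster <- as.character(roster)
  alter <- as.character(nm$alter)
  ego <- as.character(nm$ego)
  ok <- !is.na(alter) & alter != UNMATCHED & alter %in% roster &
    ego %in% roster & ego != alter
  n_unmatched <- sum(!ok)
  nm <- nm[ok, , drop = FALSE]
  kin <- if ("kin" %in% names(nm)) as.logical(nm$kin) else rep(FALSE, nrow(nm))
  if (anyNA(kin)) {
    warning(sum(is.na(kin)), " nomination(s) missing kin flag; treated as non-kin")
    kin[is.na(kin)] <- FALSE
  }
  if (generator %in% REVERSED_GENERATORS) {
    net <- directed_network(roster, from = as.character(nm$alter),
                            to = as.character(nm$ego), kin = kin,
                            layer = generator)
  } else {
    net <- directed_network(roster, from = as.character(nm$ego),
                            to = as.character(nm$alter), kin = kin,
                            layer = generator)
  }
  attr(net, "n_unmatched") <- n_unmatched
  net
}

#' Split a network into kin and non-kin layers
#'
#' @param net a [directed_network()] whose ties carry kin flags.
#' @return list with elements `kin` and `nonkin`, both on the same roster;
#'   their tie sets partition the input tie set.
#' @export
split_kin <- function(net) {
  k <- net$kin
  list(
    kin = directed_network(net$roster, net$from[k], net$to[k], TRUE,
                           layer = paste0(net$layer, "_kin")),
    nonkin = directed_network(net$roster, net$from[!k], net$to[!k], FALSE,
                              layer = paste0(net$layer, "_nonkin"))
  )
}

#' Convert to an igraph object
#'
#' @param net a [directed_network()].
#' @return a directed `igraph` graph with vertex name attributes and a
#'   logical `kin` edge attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$roster)
  if (n_ties(net)) {
    g <- igraph::add_edges(g, rbind(net$from, net$to))
    g <- igraph::set_edge_attr(g, "kin", value = net$kin)
  }
  g
}

#' Export a network layer as GraphML
#'
#' @param net a [directed_network()].
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
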