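# Minimal subsystems and their combinations — the decomposition that makes
# subnetwork-local flux analysis possible. A minimal subsystem S_Y contains
# every reaction producing Y (reversible producers contribute their producing
# direction), treats the substrates of those reactions as local label inputs,
# and holds Y's pool at steady state through an automatically added sink.

new_flux_subsystem <- function(name, network, reactions, intermediates,
                               local_inputs) {
  intermediates <- sort(unique(intermediates))
  local_inputs <- sort(setdiff(unique(local_inputs), intermediates))
  sinks <- tibble::tibble(
    id = paste0("sink_", intermediates),
    substrate = intermediates
  )
  structure(
    list(
      name = name,
      network = network,
      reactions = reactions[order(names(reactions))],
      intermediates = intermediates,
      local_inputs = local_inputs,
      sinks = sinks
    ),
    class = "flux_subsystem"
  )
}

subsystem_name_for <- function(intermediates) {
  paste0("S_", paste(sort(intermediates), collapse = ""))
}

tracer_substrates <- function(rxn) {
  mets <- vapply(rxn$substrates, `[[`, "", "met")
  keep <- vapply(rxn$substrates, function(s) length(s$atoms) > 0L, TRUE)
  unique(mets[keep])
}

tracer_products <- function(rxn) {
  mets <- vapply(rxn$products, `[[`, "", "met")
  keep <- vapply(rxn$products, function(s) length(s$atoms) > 0L, TRUE)
  unique(mets[keep])
}

#' Build the minimal subsystem of a metabolite
#'
#' Constructs S_Y: the smallest self-consistent flux model able to simulate
#' the labeling dynamics of `y`. It contains all reactions of the parent
#' network that produce `y` (for a reversible producer, only the direction
#' that forms `y`, with id suffixed `_fwd`/`_rev`), declares their substrates
#' as local label inputs, and adds a sink reaction so that the pool of `y`
#' can be held constant at any flux assignment.
#'
#' @param net A `flux_network`.
#' @param y Id of a metabolic intermediate of `net`.
#' @return A `flux_subsystem`.
#' @seealso [decompose_network()], [merge_subsystems()]
#' @export
minimal_subsystem <- function(net, y) {
  if (!y %in% net$metabolites$id) {
    stop_subflux("unknown metabolite '%s'", y)
  }
  role <- net$metabolites$role[match(y, net$metabolites$id)]
  if (role == "external") {
    stop_subflux("'%s' is external (a global input or excreted product); it has no subsystem", y)
  }
  snet <- split_reversible(net)
  prods <- producers_of(snet, y)
  if (length(prods) == 0L) {
    stop_subflux("'%s' has no producing reaction; it is a global input", y)
  }
  reactions <- snet$reactions[prods]
  inputs <- unique(unlist(lapply(reactions, tracer_substrates)))
  new_flux_subsystem(
    name = subsystem_name_for(y),
    network = net,
    reactions = reactions,
    intermediates = y,
    local_inputs = inputs
  )
}

#' Decompose a network into minimal subsystems
#'
#' One minimal subsystem per metabolic intermediate; the returned list length
#' therefore equals the number of intermediates. Co-products of a cleavage
#' reaction each get their own subsystem (same reaction set, different
#' simulated metabolite); they can be merged afterwards with
#' [merge_subsystems()] when a joint model is wanted.
#'
#' @param net A `flux_network`.
#' @return Named list of `flux_subsystem` objects (names `S_<metabolite>`).
#' @examples
#' subs <- decompose_network(example_network())
#' length(subs)
#' @export
decompose_network <- function(net) {
  inter <- intermediates_of(net)
  if (length(inter) == 0L) {
    stop_subflux("network has no metabolic intermediates")
  }
  subs <- lapply(inter, function(y) minimal_subsystem(net, y))
  names(subs) <- vapply(subs, `[[`, "", "name")
  subs
}

subsystem_metabolites <- function(s) {
  union(s$intermediates, s$local_inputs)
}

#' Merge two subsystems into a larger flux model
#'
#' Two subsystems can be combined when they share a common metabolite (e.g.
#' an intermediate of one is a local label input of the other). The merged
#' subsystem takes the union of reactions and intermediates; its local label
#' inputs are the union of the two input sets minus any metabolite that has
#' become an intermediate. Sinks are regenerated for all intermediates.
#'
#' @param s1,s2 `flux_subsystem` objects built from the same parent network.
#' @return A `flux_subsystem`.
#' @export
merge_subsystems <- function(s1, s2) {
  if (!inherits(s1, "flux_subsystem") || !inherits(s2, "flux_subsystem")) {
    stop_subflux("merge_subsystems() expects two flux_subsystem objects")
  }
  shared <- intersect(subsystem_metabolites(s1), subsystem_metabolites(s2))
  if (length(shared) == 0L) {
    stop_subflux("subsystems '%s' and '%s' share no metabolite and cannot be merged",
                 s1$name, s2$name)
  }
  reactions <- c(s1$reactions, s2$reactions[setdiff(names(s2$reactions),
                                                    names(s1$reactions))])
  intermediates <- union(s1$intermediates, s2$intermediates)
  inputs <- setdiff(union(s1$local_inputs, s2$local_inputs), intermediates)
  new_flux_subsystem(
    name = subsystem_name_for(intermediates),
    network = s1$network,
    reactions = reactions,
    intermediates = intermediates,
    local_inputs = inputs
  )
}

merge_subsystem_list <- function(subs) {
  Reduce(merge_subsystems, subs)
}

#' Enumerate the candidate subsystems of a pathway
#'
#' For a target set of reactions (typically a pathway), takes the minimal
#' subsystems of the target reactions' products as units (co-products of the
#' same cleavage reaction form one joint unit), and returns every subsystem
#' obtainable as a connected union of those units. Two units are connected
#' when they share a metabolite, the condition under which they can be
#' merged. The result is deterministic: ordered by number of reactions, then
#' by name.
#'
#' @param net A `flux_network`.
#' @param target_reactions Character vector of reaction ids forming a
#'   connected subgraph.
#' @return List of `flux_subsystem` objects.
#' @export
enumerate_pathway_subsystems <- function(net, target_reactions) {
  if (length(target_reactions) == 0L) {
    stop_subflux("empty target reaction set")
  }
  unknown <- setdiff(target_reactions, names(net$reactions))
  if (length(unknown) > 0L) {
    stop_subflux("unknown reaction id(s): %s", paste(unknown, collapse = ", "))
  }
  prods <- unique(unlist(lapply(net$reactions[target_reactions],
                                tracer_products)))
  prods <- intersect(prods, intermediates_of(net))
  units <- lapply(prods, function(y) minimal_subsystem(net, y))
  # Cleavage co-products (identical producing reaction sets) form one joint
  # unit, mirroring the use of a single S_IJ-style model for both fragments.
  sig <- vapply(units, function(s) paste(names(s$reactions), collapse = "|"), "")
  units <- lapply(split(units, sig), merge_subsystem_list)
  units <- units[order(vapply(units, `[[`, "", "name"))]
  n <- length(units)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        adj[i, j] <- length(intersect(subsystem_metabolites(units[[i]]),
                                      subsystem_metabolites(units[[j]]))) > 0L
      }
    }
  }
  if (n > 1L) {
    reach <- connected_components(adj)
    if (length(unique(reach)) > 1L) {
      stop_subflux("target reactions do not form a connected subgraph")
    }
  }
  subsets <- connected_subsets(adj)
  out <- lapply(subsets, function(idx) merge_subsystem_list(units[idx]))
  sizes <- vapply(out, function(s) length(s$reactions), 0L)
  nms <- vapply(out, `[[`, "", "name")
  out[order(sizes, nms)]
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# All connected non-empty vertex subsets of an undirected graph, enumerated
# by anchored expansion: each subset is counted once, anchored at its
# smallest vertex, and grown only through vertices larger than the anchor.
connected_subsets <- function(adj) {
  n <- nrow(adj)
  out <- list()
  grow <- function(current, frontier, anchor, forbidden) {
    out[[length(out) + 1L]] <<- sort(current)
    banned <- forbidden
    for (v in frontier) {
      if (v %in% banned) next
      nb <- which(adj[v, ])
      nb <- nb[nb > anchor & !(nb %in% current)]
      new_frontier <- setdiff(union(frontier, nb), c(current, v))
      grow(c(current, v), new_frontier, anchor, banned)
      banned <- c(banned, v)
    }
  }
  for (s in seq_len(n)) {
    nb <- which(adj[s, ])
    grow(s, nb[nb > s], s, integer())
  }
  out
}

#' @export
print.flux_subsystem <- function(x, ...) {
  cat(sprintf("<flux_subsystem> %s\n", x$name))
  cat(sprintf("  reactions:     %s\n", paste(names(x$reactions), collapse = ", ")))
  cat(sprintf("  intermediates: %s\n", paste(x$intermediates, collapse = ", ")))
  cat(sprintf("  local inputs:  %s\n", paste(x$local_inputs, collapse = ", ")))
  cat(sprintf("  sinks:         %s\n", paste(x$sinks$id, collapse = ", ")))
  invisible(x)
}
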