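# Single-atom elementary metabolite unit (EMU) decomposition. For mean
# molecular enrichment measurements, the minimal ODE system only needs
# size-1 EMUs (positional enrichments): a backward traversal from the
# measured metabolites collects exactly the atom positions whose balance
# equations are required, and identifies which local-input EMUs must be
# supplied as time-functions.

#' Decompose a subsystem into the EMUs needed for a measurement set
#'
#' Walks backward from the measured metabolites (mean molecular enrichment,
#' i.e. all atom positions) through the subsystem's atom maps, collecting the
#' size-1 EMUs that must be simulated and the local-input EMUs that force the
#' system. Node ordering is deterministic (metabolite, then position).
#'
#' @param sub A `flux_subsystem`.
#' @param measured Character vector of measured intermediates (defaults to
#'   all intermediates of the subsystem).
#' @return An `emu_network`: tibbles `states` (simulated EMUs), `inputs`
#'   (forcing EMUs on local inputs) and `edges` (flux-weighted production
#'   relations `reaction, metabolite, position, from_met, from_pos,
#'   from_type`).
#' @export
emu_decompose <- function(sub, measured = sub$intermediates) {
  stopifnot(inherits(sub, "flux_subsystem"))
  outside <- setdiff(measured, sub$intermediates)
  if (length(outside) > 0L) {
    stop_subflux("measured metabolite(s) outside the subsystem intermediates: %s",
                 paste(outside, collapse = ", "))
  }
  net <- sub$network
  key <- function(met, pos) paste0(met, "#", pos)
  queue <- list()
  for (m in sort(measured)) {
    for (p in seq_len(met_atoms(net, m))) {
      queue[[length(queue) + 1L]] <- list(met = m, pos = p)
    }
  }
  seen <- character()
  states <- list()
  inputs <- list()
  edges <- list()
  while (length(queue) > 0L) {
    node <- queue[[1]]
    queue <- queue[-1]
    k <- key(node$met, node$pos)
    if (k %in% seen) next
    seen <- c(seen, k)
    states[[k]] <- node
    for (rxn in sub$reactions) {
      for (prod in rxn$products) {
        if (prod$met != node$met || length(prod$atoms) < node$pos) next
        label <- prod$atoms[[node$pos]]
        src <- find_atom_source(rxn, label)
        from_type <- if (src$met %in% sub$intermediates) "state" else "input"
        edges[[length(edges) + 1L]] <- tibble::tibble(
          reaction = rxn$id,
          metabolite = node$met,
          position = node$pos,
          from_met = src$met,
          from_pos = src$pos,
          from_type = from_type
        )
        if (from_type == "state") {
          queue[[length(queue) + 1L]] <- list(met = src$met, pos = src$pos)
        } else {
          inputs[[key(src$met, src$pos)]] <- list(met = src$met, pos = src$pos)
        }
      }
    }
  }
  to_tbl <- function(lst) {
    if (length(lst) == 0L) {
      return(tibble::tibble(metabolite = character(), position = integer()))
    }
    tbl <- tibble::tibble(
      metabolite = unname(vapply(lst, `[[`, "", "met")),
      position = unname(vapply(lst, function(x) as.integer(x$pos), 0L))
    )
    tbl[order(tbl$metabolite, tbl$position), ]
  }
  edges_tbl <- if (length(edges) > 0L) dplyr::bind_rows(edges) else
    tibble::tibble(reaction = character(), metabolite = character(),
                   position = integer(), from_met = character(),
                   from_pos = integer(), from_type = character())
  structure(
    list(
      states = to_tbl(states),
      inputs = to_tbl(inputs[!duplicated(names(inputs))]),
      edges = edges_tbl[order(edges_tbl$metabolite, edges_tbl$position,
                              edges_tbl$reaction), ],
      measured = sort(measured),
      subsystem = sub$name
    ),
    class = "emu_network"
  )
}

find_atom_source <- function(rxn, label) {
  for (s in rxn$substrates) {
    j <- match(label, s$atoms)
    if (!is.na(j)) {
      return(list(met = s$met, pos = j))
    }
  }
  stop_subflux("reaction '%s': atom label '%s' has no substrate source",
               rxn$id, label)
}

#' Identify which local-input measurements a flux model needs
#'
#' Returns, per local label input, the atom positions whose labeling
#' time-course must be supplied for the subsystem simulation to be
#' computable. When only a subset of an input's atoms is needed (the product
#' is a cleavage fragment), the requirement is flagged as a `fragment`:
#' matching fragment data (e.g. MS/MS) or positional data identify the flux
#' exactly, while a metabolite-level mean enrichment curve is only a proxy.
#' If `available` lists the measurable metabolites, requirements outside the
#' list are flagged unresolvable rather than raising an error; merging the
#' subsystem with an upstream one often restores resolvability.
#'
#' @inheritParams emu_decompose
#' @param available Optional character vector of metabolites with measurable
#'   labeling dynamics.
#' @return A tibble with one row per required input: `metabolite`,
#'   `positions` (list-column), `n_required`, `n_atoms`, `fragment`,
#'   `measurable`, `resolvable`.
#' @export
required_measurements <- function(sub, measured = sub$intermediates,
                                  available = NULL) {
  emu <- emu_decompose(sub, measured)
  inp <- emu$inputs
  if (nrow(inp) == 0L) {
    return(tibble::tibble(
      metabolite = character(), positions = list(), n_required = integer(),
      n_atoms = integer(), fragment = logical(), measurable = logical(),
      resolvable = logical()
    ))
  }
  out <- inp |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(positions = list(sort(.data$position)),
                     n_required = dplyr::n(), .groups = "drop")
  out$n_atoms <- unname(vapply(out$metabolite,
                               function(m) met_atoms(sub$network, m), 0L))
  out$fragment <- out$n_required < out$n_atoms
  out$measurable <- if (is.null(available)) NA else out$metabolite %in% available
  out$resolvable <- is.na(out$measurable) | out$measurable
  out
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network> %s: %d simulated EMUs, %d input EMUs, %d edges\n",
              x$subsystem, nrow(x$states), nrow(x$inputs), nrow(x$edges)))
  invisible(x)
}
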