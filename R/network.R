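# Atom-mapped metabolic networks: parsing, validation, writing, and the
# elementary queries every other module builds on.
#
# Reaction-file format (tab-separated, '#' comments):
#   @external X_out [more ids ...]
#   reaction_id <TAB> Met1[abc] + Met2[d] -> Met3[dabc] <TAB> reversible(0|1)
# Atom labels are lowercase letters, one per tracer atom, 1-based in the order
# written. Atom-free species (cofactors) are written without brackets and may
# carry a stoichiometric coefficient; tracer-carrying species always have
# coefficient 1 per occurrence.

TERM_RE <- "^(?:([0-9]+(?:\\.[0-9]+)?)\\s+)?([A-Za-z][A-Za-z0-9_]*)(?:\\[([a-z]+)\\])?$"

parse_species_term <- function(term, line_no) {
  m <- regmatches(term, regexec(TERM_RE, term))[[1]]
  if (length(m) == 0L) {
    stop_subflux("line %d: cannot parse species term '%s'", line_no, term)
  }
  coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
  atoms <- if (nzchar(m[4])) strsplit(m[4], "")[[1]] else character()
  if (coef <= 0) {
    stop_subflux("line %d: stoichiometric coefficient must be > 0", line_no)
  }
  if (length(atoms) > 0L && coef != 1) {
    stop_subflux(
      "line %d: tracer-carrying species '%s' must have coefficient 1 (write the species twice for 2x)",
      line_no, m[3]
    )
  }
  list(met = m[3], coef = coef, atoms = atoms)
}

parse_side <- function(side, line_no) {
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) {
    stop_subflux("line %d: empty reaction side", line_no)
  }
  lapply(terms, parse_species_term, line_no = line_no)
}

side_atoms <- function(side) {
  unlist(lapply(side, function(s) s$atoms), use.names = FALSE)
}

validate_reaction <- function(rxn, line_no = NA_integer_) {
  where <- if (is.na(line_no)) rxn$id else sprintf("line %d (%s)", line_no, rxn$id)
  sub_atoms <- side_atoms(rxn$substrates)
  prod_atoms <- side_atoms(rxn$products)
  if (anyDuplicated(sub_atoms)) {
    stop_subflux("%s: duplicate atom label on substrate side", where)
  }
  if (anyDuplicated(prod_atoms)) {
    stop_subflux("%s: duplicate atom label on product side", where)
  }
  missing_src <- setdiff(prod_atoms, sub_atoms)
  if (length(missing_src) > 0L) {
    stop_subflux("%s: product atom(s) %s have no substrate source",
                 where, paste(missing_src, collapse = ", "))
  }
  lost <- setdiff(sub_atoms, prod_atoms)
  if (length(lost) > 0L) {
    stop_subflux("%s: substrate atom(s) %s do not appear in any product",
                 where, paste(lost, collapse = ", "))
  }
  invisible(rxn)
}

build_metabolite_table <- function(reactions, external) {
  occ <- list()
  for (rxn in reactions) {
    for (s in c(rxn$substrates, rxn$products)) {
      occ[[length(occ) + 1L]] <- list(met = s$met, n = length(s$atoms))
    }
  }
  ids <- vapply(occ, `[[`, "", "met")
  ns <- vapply(occ, `[[`, 0L, "n")
  for (id in unique(ids)) {
    if (length(unique(ns[ids == id])) > 1L) {
      stop_subflux("inconsistent atom count for metabolite '%s'", id)
    }
  }
  unknown_ext <- setdiff(external, ids)
  if (length(unknown_ext) > 0L) {
    stop_subflux("@external declares unknown metabolite(s): %s",
                 paste(unknown_ext, collapse = ", "))
  }
  tab <- tibble::tibble(
    id = unique(ids),
    n_atoms = ns[!duplicated(ids)],
    role = ifelse(unique(ids) %in% external, "external", "intermediate")
  )
  tab[order(tab$id), ]
}

new_flux_network <- function(metabolites, reactions) {
  structure(list(metabolites = metabolites, reactions = reactions),
            class = "flux_network")
}

#' Parse an atom-mapped reaction file
#'
#' Reads the tab-separated reaction format into a validated network object.
#' Each non-comment line is `id <TAB> equation <TAB> reversible(0|1)`, with
#' equations like `G[ab] + K[cd] -> H[abcd]`; a header block of
#' `@external <id> ...` lines declares which metabolites lie outside the
#' modeled boundary (the global nutrient and excreted products). Atom maps are
#' stored 1-based in the order written. Every metabolite not declared external
#' must be produced by at least one reaction.
#'
#' @param text A single string (possibly multi-line) or character vector of
#'   lines with the reaction-file content.
#' @return A `flux_network` object with elements `metabolites` (tibble:
#'   `id`, `n_atoms`, `role`) and `reactions` (named list).
#' @seealso [write_network()], [read_network()], [producers_of()],
#'   [split_reversible()]
#' @examples
#' net <- parse_network(c("@external X", "r1\tX[ab] -> A[ab]\t0"))
#' net$metabolites
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  external <- character()
  reactions <- list()
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "@external")) {
      ids <- strsplit(line, "[ \t]+")[[1]][-1]
      external <- c(external, ids)
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields[nzchar(trimws(fields))])
    if (length(fields) != 3L) {
      stop_subflux("line %d: expected 'id <TAB> equation <TAB> reversible', got '%s'",
                   i, line)
    }
    id <- fields[[1]]
    if (id %in% names(reactions)) {
      stop_subflux("line %d: duplicate reaction id '%s'", i, id)
    }
    if (!fields[[3]] %in% c("0", "1")) {
      stop_subflux("line %d: reversible flag must be 0 or 1", i)
    }
    sides <- strsplit(fields[[2]], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) {
      stop_subflux("line %d: equation must contain exactly one '->'", i)
    }
    rxn <- list(
      id = id,
      substrates = parse_side(sides[[1]], i),
      products = parse_side(sides[[2]], i),
      reversible = fields[[3]] == "1"
    )
    validate_reaction(rxn, i)
    reactions[[id]] <- rxn
  }
  if (length(reactions) == 0L) {
    stop_subflux("no reactions found")
  }
  metabolites <- build_metabolite_table(reactions, unique(external))
  net <- new_flux_network(metabolites, reactions)
  validate_network(net)
  net
}

#' Read an atom-mapped reaction file from disk
#'
#' @param path Path to a reaction file in the format of [parse_network()].
#' @return A `flux_network`.
#' @export
read_network <- function(path) {
  parse_network(readLines(path, warn = FALSE))
}

validate_network <- function(net) {
  inter <- net$metabolites$id[net$metabolites$role == "intermediate"]
  for (y in inter) {
    if (length(producers_of(net, y)) == 0L) {
      stop_subflux(
        "metabolite '%s' is never produced; declare it '@external' if it lies outside the network boundary",
        y
      )
    }
  }
  invisible(net)
}

format_species_term <- function(s) {
  base <- if (length(s$atoms) > 0L) {
    sprintf("%s[%s]", s$met, paste(s$atoms, collapse = ""))
  } else {
    s$met
  }
  if (s$coef != 1) paste(format(s$coef), base) else base
}

format_reaction_equation <- function(rxn) {
  paste(
    paste(vapply(rxn$substrates, format_species_term, ""), collapse = " + "),
    "->",
    paste(vapply(rxn$products, format_species_term, ""), collapse = " + ")
  )
}

#' Write a network back to the reaction-file format
#'
#' The output round-trips: `parse_network(write_network(net))` reproduces the
#' network, including reversible flags and external-role declarations.
#'
#' @param net A `flux_network`.
#' @param path Optional file path; when given, the content is also written to
#'   disk.
#' @return The reaction-file content as a single string (invisibly when
#'   `path` is given).
#' @export
write_network <- function(net, path = NULL) {
  ext <- net$metabolites$id[net$metabolites$role == "external"]
  lines <- character()
  if (length(ext) > 0L) {
    lines <- sprintf("@external %s", paste(sort(ext), collapse = " "))
  }
  for (rxn in net$reactions) {
    lines <- c(lines, sprintf("%s\t%s\t%d", rxn$id,
                              format_reaction_equation(rxn),
                              as.integer(rxn$reversible)))
  }
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.flux_network <- function(x, ...) {
  n_rev <- sum(vapply(x$reactions, `[[`, TRUE, "reversible"))
  cat(sprintf(
    "<flux_network> %d metabolites (%d intermediates), %d reactions (%d reversible)\n",
    nrow(x$metabolites),
    sum(x$metabolites$role == "intermediate"),
    length(x$reactions), n_rev
  ))
  invisible(x)
}

met_atoms <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop_subflux("unknown metabolite '%s'", id)
  net$metabolites$n_atoms[[i]]
}

intermediates_of <- function(net) {
  net$metabolites$id[net$metabolites$role == "intermediate"]
}

#' Reactions producing a metabolite
#'
#' Returns the ids of all reactions with `y` among their products. The reverse
#' direction of a reversible reaction counts as a producer of its substrates,
#' so a reversible reaction B <-> C is reported as a producer of both B and C.
#'
#' @param net A `flux_network`.
#' @param y Metabolite id.
#' @return Sorted character vector of reaction ids (empty for a global input).
#' @export
producers_of <- function(net, y) {
  if (!y %in% net$metabolites$id) {
    stop_subflux("unknown metabolite '%s'", y)
  }
  out <- character()
  for (rxn in net$reactions) {
    prod_mets <- vapply(rxn$products, `[[`, "", "met")
    sub_mets <- vapply(rxn$substrates, `[[`, "", "met")
    if (y %in% prod_mets || (rxn$reversible && y %in% sub_mets)) {
      out <- c(out, rxn$id)
    }
  }
  sort(unique(out))
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reversible reaction is replaced by two irreversible reactions with
#' ids suffixed `_fwd` and `_rev`; the reverse direction swaps substrate and
#' product sides (atom maps mirrored accordingly). Irreversible reactions are
#' unchanged and the operation is idempotent.
#'
#' @param net A `flux_network`.
#' @return A `flux_network` with no reversible reactions.
#' @export
split_reversible <- function(net) {
  reactions <- list()
  for (rxn in net$reactions) {
    if (!rxn$reversible) {
      reactions[[rxn$id]] <- rxn
    } else {
      fwd <- rxn
      fwd$id <- paste0(rxn$id, "_fwd")
      fwd$reversible <- FALSE
      rev <- rxn
      rev$id <- paste0(rxn$id, "_rev")
      rev$reversible <- FALSE
      rev$substrates <- rxn$products
      rev$products <- rxn$substrates
      reactions[[fwd$id]] <- fwd
      reactions[[rev$id]] <- rev
    }
  }
  new_flux_network(net$metabolites, reactions)
}
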