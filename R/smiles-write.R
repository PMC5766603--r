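## SMILES output for reporting, and connected-component utilities.

# connected components as separate molecules
split_components <- function(mol, id_prefix = "component") {
  n <- n_atoms(mol)
  if (n == 0L) return(list())
  adj <- .adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      for (b in adj[[a]]$nbr) {
        if (comp[b] == 0L) { comp[b] <- cur; queue <- c(queue, b) }
      }
    }
  }
  lapply(seq_len(cur), function(k) {
    keep <- which(comp == k)
    remap <- stats::setNames(seq_along(keep), keep)
    b <- mol$bonds[mol$bonds$from %in% keep & mol$bonds$to %in% keep, ]
    molecule(mol$atoms[keep, ],
             tibble(from = unname(remap[as.character(b$from)]),
                    to = unname(remap[as.character(b$to)]),
                    order = b$order),
             id = paste0(id_prefix, k))
  })
}

#' Write a molecule as a SMILES string
#'
#' Produces a deterministic SMILES for reporting: the traversal is rooted and
#' ordered by the atoms' canonical labels at moiety size 3, so isomorphic
#' inputs yield identical strings up to automorphism. Explicit hydrogens are
#' folded back into implicit counts; atoms with charges or non-default
#' hydrogen counts are bracketed.
#'
#' @param mol a `molecule`.
#' @param registry registry used for canonical ordering.
#' @return A SMILES string (components separated by `.`).
#' @export
write_smiles <- function(mol, registry = default_registry()) {
  comps <- split_components(mol)
  paste(vapply(comps, function(m) .component_smiles(m, registry), character(1)),
        collapse = ".")
}

.component_smiles <- function(mol, registry) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  q <- mol$atoms$charge
  adj <- .adjacency(mol)
  # fold neutral single-bonded H into heavy-atom hydrogen counts
  is_h <- el == "H" & q == 0L
  deg <- vapply(seq_len(n), function(a) length(adj[[a]]$nbr), integer(1))
  fold <- is_h & deg == 1L
  if (all(fold)) {
    # H2 or a bare hydrogen record: emit bracket atoms directly
    return(paste(rep("[H]", n), collapse = if (n == 2L) "" else "."))
  }
  labs <- atom_labels(mol, 3, registry)
  rank <- rank(labs$key, ties.method = "first")
  heavy <- which(!fold)
  hcount <- integer(n)
  for (a in heavy) {
    hn <- adj[[a]]$nbr[fold[adj[[a]]$nbr]]
    hcount[a] <- length(hn)
  }
  arom <- vapply(seq_len(n), function(a) any(adj[[a]]$order == AROMATIC),
                 logical(1))

  visited <- rep(FALSE, n)
  ring_id <- 0L
  ring_open <- list()  # key "i|j" -> number
  # classify tree/back edges by DFS over heavy atoms
  emit <- function(a, from) {
    visited[a] <<- TRUE
    nbrs <- adj[[a]]$nbr; ords <- adj[[a]]$order
    keep <- !fold[nbrs] & nbrs != (from %||% -1L)
    nbrs <- nbrs[keep]; ords <- ords[keep]
    o <- order(rank[nbrs])
    nbrs <- nbrs[o]; ords <- ords[o]
    ringpart <- ""
    branches <- character(0)
    for (t in seq_along(nbrs)) {
      b <- nbrs[t]; bo <- ords[t]
      ekey <- paste(sort(c(a, b)), collapse = "|")
      if (visited[b]) {
        if (!is.null(ring_open[[ekey]])) {
          ringpart <- paste0(ringpart, .bond_sym(bo, arom[a], arom[b]),
                             .ring_token(ring_open[[ekey]]))
        }
        next
      }
      # reserve ring numbers for back edges discovered later
      branches <- c(branches, paste0(.bond_sym(bo, arom[a], arom[b]),
                                     emit(b, a)))
    }
    # open ring numbers for back edges from a to already-unvisited... handled
    paste0(.atom_token(a, el, q, hcount, arom, adj), ringpart,
           if (length(branches) > 1L) {
             paste0(paste0("(", branches[-length(branches)], ")", collapse = ""),
                    branches[length(branches)])
           } else paste0(branches, collapse = ""))
  }
  # precompute back edges: DFS order by rank
  # (two passes: first find back edges, then emit with ring numbers)
  parent <- rep(NA_integer_, n)
  order_visit <- integer(0)
  seen <- rep(FALSE, n)
  back_edges <- character(0)
  dfs <- function(a, from) {
    seen[a] <<- TRUE
    order_visit <<- c(order_visit, a)
    nbrs <- adj[[a]]$nbr
    keep <- !fold[nbrs] & nbrs != (from %||% -1L)
    nbrs <- nbrs[keep][order(rank[nbrs[keep]])]
    for (b in nbrs) {
      ekey <- paste(sort(c(a, b)), collapse = "|")
      if (seen[b]) {
        if (!ekey %in% back_edges && !identical(parent[a], b)) {
          back_edges <<- c(back_edges, ekey)
        }
      } else {
        parent[b] <<- a
        dfs(b, a)
      }
    }
  }
  root <- heavy[order(rank[heavy])][1]
  dfs(root, NULL)
  for (k in seq_along(back_edges)) ring_open[[back_edges[k]]] <- k
  visited <- rep(FALSE, n)
  out <- emit(root, NULL)
  out
}

.ring_token <- function(k) if (k < 10L) as.character(k) else sprintf("%%%02d", k)

.bond_sym <- function(o, arom_a, arom_b) {
  if (o == 2) "="
  else if (o == 3) "#"
  else if (o == AROMATIC) { if (arom_a && arom_b) "" else ":" }
  else ""
}

.atom_token <- function(a, el, q, hcount, arom, adj) {
  e <- el[a]
  sym <- if (arom[a] && tolower(e) %in% c("b", "c", "n", "o", "p", "s")) {
    tolower(e)
  } else e
  # default implicit-H fill given the heavy-bond orders
  osum <- sum(adj[[a]]$order)
  hfill_default <- .implicit_h(e, q[a], osum - hcount[a])
  plain <- q[a] == 0L && nchar(e) <= 2L && e %in% .ORGANIC &&
    hcount[a] == hfill_default
  if (plain && !arom[a]) return(sym)
  if (plain && arom[a]) return(sym)
  hh <- if (hcount[a] == 0L) "" else if (hcount[a] == 1L) "H" else paste0("H", hcount[a])
  qq <- if (q[a] == 0L) "" else if (q[a] > 0L) {
    if (q[a] == 1L) "+" else paste0("+", q[a])
  } else {
    if (q[a] == -1L) "-" else paste0("-", abs(q[a]))
  }
  paste0("[", sym, hh, qq, "]")
}

#' Write molecules to an SDF file
#'
#' V2000 records (aromatic bonds as type 4, charges as `M  CHG`), hydrogens
#' written explicitly, records separated by `$$$$`.
#'
#' @param mols list of `molecule` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  recs <- vapply(mols, .molfile_text, character(1))
  writeLines(c(paste(recs, collapse = "\n$$$$\n"), "$$$$"), path)
  invisible(path)
}

.molfile_text <- function(mol) {
  na <- n_atoms(mol); nb <- nrow(mol$bonds)
  hdr <- c(mol$id %||% "", "  moietypath", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atoms <- vapply(seq_len(na), function(a) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$atoms$element[a])
  }, character(1))
  bonds <- vapply(seq_len(nb), function(k) {
    o <- mol$bonds$order[k]
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$from[k], mol$bonds$to[k],
            if (o == AROMATIC) 4L else as.integer(o))
  }, character(1))
  chg <- which(mol$atoms$charge != 0L)
  props <- if (length(chg) > 0L) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(hdr, counts, atoms, bonds, props, "M  END"), collapse = "\n")
}
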