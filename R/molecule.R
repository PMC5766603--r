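#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Bond orders are numeric: 1, 2, 3 and 1.5 for aromatic bonds. Aromatic bonds
# are never kekulized so that resonance-equivalent atoms receive equal labels.
AROMATIC <- 1.5

# Allowed valences used both for implicit-hydrogen fill and for screening
# candidate products during rule application.
.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, Se = c(2L, 4L, 6L)
)

.PERIODIC <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S","Cl",
  "Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga","Ge","As",
  "Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd","Ag","Cd","In",
  "Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm","Sm","Eu","Gd","Tb",
  "Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os","Ir","Pt","Au","Hg","Tl",
  "Pb","Bi","Po","At","Rn"
)

#' Construct a molecule from atom and bond tables
#'
#' A molecule is a labeled graph: atoms carry an element symbol and a formal
#' charge, bonds carry an order (1, 2, 3, or 1.5 for aromatic). Hydrogens are
#' explicit nodes; the parsers expand implicit hydrogens before returning.
#'
#' @param atoms tibble with columns `element` (character) and `charge`
#'   (integer); rows are atoms, row number is the atom index.
#' @param bonds tibble with columns `from`, `to` (atom indices) and `order`.
#' @param id metabolite identifier.
#' @param source optional source text the molecule was parsed from.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds, id = NA_character_, source = NA_character_) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  if (!all(c("element", "charge") %in% names(atoms))) {
    abort("`atoms` needs columns element, charge")
  }
  if (nrow(bonds) == 0L) {
    bonds <- tibble(from = integer(), to = integer(), order = numeric())
  }
  if (!all(c("from", "to", "order") %in% names(bonds))) {
    abort("`bonds` needs columns from, to, order")
  }
  bad <- setdiff(atoms$element, .PERIODIC)
  if (length(bad) > 0L) {
    abort(paste0("unsupported element symbol(s): ", paste(bad, collapse = ", ")))
  }
  n <- nrow(atoms)
  if (nrow(bonds) > 0L && (any(bonds$from < 1L | bonds$from > n) ||
                           any(bonds$to < 1L | bonds$to > n))) {
    abort("bond references a non-existent atom")
  }
  structure(
    list(
      id = id,
      atoms = tibble(element = as.character(atoms$element),
                     charge = as.integer(atoms$charge)),
      bonds = tibble(from = as.integer(bonds$from), to = as.integer(bonds$to),
                     order = as.numeric(bonds$order)),
      source = source
    ),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds>\n",
              x$id %||% "?", nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# adjacency: list per atom of tibble(nbr, order)
.adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- replicate(n, list(nbr = integer(), order = numeric()), simplify = FALSE)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$from[k]; j <- b$to[k]; o <- b$order[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
  }
  adj
}

# smallest allowed valence >= bonded order sum; NA when the element has no
# tabulated valence (then no H are filled)
.implicit_h <- function(element, charge, order_sum) {
  v <- .VALENCES[[element]]
  if (is.null(v) || charge != 0L) return(0L)
  need <- ceiling(order_sum - 1e-9)
  v <- v[v >= need]
  if (length(v) == 0L) return(0L)
  as.integer(v[1] - need)
}

# append explicit hydrogen atoms according to `hfill` counts per atom
.expand_h <- function(atoms, bonds, hfill) {
  n0 <- nrow(atoms)
  extra <- sum(hfill)
  if (extra > 0L) {
    atoms <- dplyr::bind_rows(atoms,
      tibble(element = rep("H", extra), charge = rep(0L, extra)))
    idx <- n0
    newb <- vector("list", sum(hfill > 0L))
    kk <- 1L
    for (i in which(hfill > 0L)) {
      js <- idx + seq_len(hfill[i]); idx <- idx + hfill[i]
      newb[[kk]] <- tibble(from = rep(i, length(js)), to = js,
                           order = rep(1, length(js)))
      kk <- kk + 1L
    }
    bonds <- dplyr::bind_rows(bonds, newb)
  }
  list(atoms = atoms, bonds = bonds)
}

#' Parse a molecular structure
#'
#' Reads a single structure from SMILES or MDL molfile (V2000) text and returns
#' a molecule with all hydrogens made explicit. Aromatic bonds (lowercase
#' SMILES atoms, molfile bond type 4) are retained as a distinct order so that
#' resonance-equivalent atoms later receive identical canonical labels.
#'
#' @param text the structure as a single string (a SMILES, or the full molfile
#'   text including newlines).
#' @param dialect `"smiles"` or `"molfile"`.
#' @param id metabolite identifier attached to the result.
#' @return A `molecule`.
#' @examples
#' parse_structure("O=C=O", id = "co2")
#' parse_structure("c1ccccc1O", id = "phenol")
#' @export
parse_structure <- function(text, dialect = c("smiles", "molfile"),
                            id = NA_character_) {
  dialect <- match.arg(dialect)
  switch(dialect,
         smiles = .parse_smiles(text, id),
         molfile = .parse_molfile(text, id))
}

## ---- SMILES ---------------------------------------------------------------

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.parse_smiles <- function(text, id = NA_character_) {
  s <- trimws(text)
  if (nchar(s) == 0L) abort("empty SMILES string")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  element <- character(); charge <- integer(); arom <- logical()
  hexp <- integer()   # explicit H count for bracket atoms, NA = fill
  from <- integer(); to <- integer(); order <- numeric()

  prev <- NA_integer_          # previous atom index
  stack <- integer()           # branch stack
  pend <- NA_real_             # pending bond order
  ring <- list()               # ring-closure bookkeeping

  add_atom <- function(el, q, ar, hh) {
    element[length(element) + 1L] <<- el
    charge[length(charge) + 1L] <<- q
    arom[length(arom) + 1L] <<- ar
    hexp[length(hexp) + 1L] <<- hh
    length(element)
  }
  add_bond <- function(i, j, o) {
    from[length(from) + 1L] <<- i; to[length(to) + 1L] <<- j
    order[length(order) + 1L] <<- o
  }
  link <- function(idx) {
    if (!is.na(prev)) {
      o <- pend
      if (is.na(o)) o <- if (arom[prev] && arom[idx]) AROMATIC else 1
      add_bond(prev, idx, o)
    }
    prev <<- idx; pend <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) abort(sprintf("SMILES parse error near '%s': unclosed bracket",
                               substr(s, i, min(n, i + 6L))))
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?((\\+{1,3}|-{1,3})([0-9]*))?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("SMILES parse error: cannot read bracket atom '[%s]'", body))
      }
      sym <- m[3]
      ar <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      el <- if (ar) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
      if (!el %in% .PERIODIC) {
        abort(sprintf("unsupported element '%s' in SMILES", el))
      }
      hh <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      q <- 0L
      if (nzchar(m[7])) {
        sgn <- if (substr(m[8], 1, 1) == "+") 1L else -1L
        q <- if (nzchar(m[9])) sgn * as.integer(m[9]) else sgn * nchar(m[8])
      }
      idx <- add_atom(el, q, ar, hh)
      link(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), 0L, FALSE, NA_integer_)
      link(idx); i <- i + 2L
    } else if (ch %in% .ORGANIC) {
      idx <- add_atom(ch, 0L, FALSE, NA_integer_)
      link(idx); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), 0L, TRUE, NA_integer_)
      link(idx); i <- i + 1L
    } else if (ch == "-") { pend <- 1; i <- i + 1L
    } else if (ch == "=") { pend <- 2; i <- i + 1L
    } else if (ch == "#") { pend <- 3; i <- i + 1L
    } else if (ch == ":") { pend <- AROMATIC; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pend <- 1; i <- i + 1L  # stereo bonds read as single
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) abort("SMILES parse error: unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- NA_integer_; pend <- NA_real_; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) abort("SMILES parse error: truncated % ring closure")
        num <- substr(s, i + 1L, i + 2L); i <- i + 3L
      } else { num <- ch; i <- i + 1L }
      if (is.na(prev)) abort("SMILES parse error: ring closure before any atom")
      if (!is.null(ring[[num]])) {
        op <- ring[[num]]
        o <- pend
        if (is.na(o)) o <- op$order
        if (is.na(o)) o <- if (arom[op$atom] && arom[prev]) AROMATIC else 1
        add_bond(op$atom, prev, o)
        ring[[num]] <- NULL
      } else {
        ring[[num]] <- list(atom = prev, order = pend)
      }
      pend <- NA_real_
    } else if (ch == "@") { i <- i + 1L  # chirality ignored (out of scope)
    } else {
      abort(sprintf("SMILES parse error at position %d: unexpected '%s'", i, ch))
    }
  }
  if (length(ring) > 0L) abort("SMILES parse error: unclosed ring bond")
  if (length(stack) > 0L) abort("SMILES parse error: unmatched '('")
  if (length(element) == 0L) abort("SMILES parse error: no atoms")

  atoms <- tibble(element = element, charge = charge)
  bonds <- tibble(from = from, to = to, order = order)
  osum <- numeric(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    osum[bonds$from[k]] <- osum[bonds$from[k]] + bonds$order[k]
    osum[bonds$to[k]] <- osum[bonds$to[k]] + bonds$order[k]
  }
  hfill <- integer(nrow(atoms))
  for (a in seq_len(nrow(atoms))) {
    hfill[a] <- if (is.na(hexp[a])) {
      .implicit_h(element[a], charge[a], osum[a])
    } else hexp[a]
  }
  g <- .expand_h(atoms, bonds, hfill)
  molecule(g$atoms, g$bonds, id = id, source = text)
}

## ---- MDL molfile (V2000) --------------------------------------------------

.parse_molfile <- function(text, id = NA_character_) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L) abort("molfile parse error: fewer than 4 header lines")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) {
    abort(sprintf("molfile parse error: bad counts line '%s'", counts))
  }
  if (length(lines) < 4L + na + nb) abort("molfile parse error: truncated atom/bond block")
  at <- lines[4L + seq_len(na)]
  el <- trimws(substr(at, 32, 34))
  bad <- setdiff(el, .PERIODIC)
  if (length(bad) > 0L) {
    abort(paste0("unsupported element symbol(s) in molfile: ",
                 paste(bad, collapse = ", ")))
  }
  ccode <- suppressWarnings(as.integer(substr(at, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  chg <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)[as.character(ccode)]
  chg[is.na(chg)] <- 0L
  bl <- lines[4L + na + seq_len(nb)]
  b1 <- as.integer(substr(bl, 1, 3)); b2 <- as.integer(substr(bl, 4, 6))
  bt <- as.integer(substr(bl, 7, 9))
  if (any(is.na(b1) | is.na(b2) | is.na(bt))) {
    abort("molfile parse error: malformed bond line")
  }
  ord <- ifelse(bt == 4L, AROMATIC, as.numeric(bt))
  if (any(!bt %in% c(1L, 2L, 3L, 4L))) {
    abort(sprintf("molfile parse error: unsupported bond type %s",
                  paste(setdiff(bt, 1:4), collapse = ",")))
  }
  # M CHG property lines override the atom-block charge column
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- scan(text = substr(ln, 7, nchar(ln)), quiet = TRUE)
    nset <- f[1]
    for (k in seq_len(nset)) chg[f[2 * k]] <- as.integer(f[2 * k + 1])
  }
  atoms <- tibble(element = el, charge = as.integer(chg))
  bonds <- tibble(from = b1, to = b2, order = ord)
  osum <- numeric(na)
  for (k in seq_len(nb)) {
    osum[b1[k]] <- osum[b1[k]] + ord[k]; osum[b2[k]] <- osum[b2[k]] + ord[k]
  }
  hfill <- integer(na)
  for (a in seq_len(na)) {
    if (el[a] != "H") hfill[a] <- .implicit_h(el[a], atoms$charge[a], osum[a])
  }
  g <- .expand_h(atoms, bonds, hfill)
  molecule(g$atoms, g$bonds, id = id, source = paste(lines, collapse = "\n"))
}

## ---- structure files ------------------------------------------------------

#' Read a table of structures
#'
#' Reads either a SMILES table (TSV with columns `id` and `smiles`) or an SDF
#' file (records separated by `$$$$`, id taken from the title line) and returns
#' a named list of molecules.
#'
#' @param path file path.
#' @param format `"smiles"`, `"sdf"`, or `"auto"` (by file extension).
#' @return Named list of `molecule` objects.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("id", "smiles") %in% names(tab))) {
      abort("SMILES table needs columns `id` and `smiles`")
    }
    mols <- purrr::map2(tab$smiles, tab$id, ~ .parse_smiles(.x, id = .y))
    stats::setNames(mols, tab$id)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
    recs <- recs[trimws(recs) != ""]
    mols <- purrr::map(recs, function(r) {
      lines <- strsplit(sub("^\n+", "", r), "\n")[[1]]
      .parse_molfile(lines, id = trimws(lines[1]))
    })
    stats::setNames(mols, purrr::map_chr(mols, "id"))
  }
}

## ---- element counts -------------------------------------------------------

#' Count atoms per element
#'
#' @param mol a `molecule`.
#' @return A tibble with columns `element` and `count`, sorted by element;
#'   counts sum to the number of atoms and are invariant under any permutation
#'   of atom indices.
#' @export
element_counts <- function(mol) {
  tab <- table(mol$atoms$element)
  tibble(element = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(.data$element)
}

# named integer vector form used in balance arithmetic
.elem_vec <- function(mol) {
  tab <- table(mol$atoms$element)
  stats::setNames(as.integer(tab), names(tab))
}

# add scaled element vectors: sum_k coef[k] * vec[[k]]
.elem_sum <- function(vecs, coefs) {
  els <- sort(unique(unlist(lapply(vecs, names))))
  out <- stats::setNames(numeric(length(els)), els)
  for (k in seq_along(vecs)) {
    v <- vecs[[k]]
    out[names(v)] <- out[names(v)] + coefs[k] * v
  }
  out
}

#' Molecular formula as a compact string (Hill order)
#' @param mol a `molecule`.
#' @return A single string such as `"C7H6O3"`.
#' @export
molecular_formula <- function(mol) {
  v <- .elem_vec(mol)
  els <- names(v)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(purrr::map_chr(hill, function(e) {
    paste0(e, if (v[[e]] > 1L) v[[e]] else "")
  }), collapse = "")
}

# disjoint union of two molecules (salts / multi-component records)
.mol_union <- function(a, b, id = NA_character_) {
  off <- n_atoms(a)
  molecule(
    dplyr::bind_rows(a$atoms, b$atoms),
    dplyr::bind_rows(a$bonds,
                     dplyr::mutate(b$bonds, from = .data$from + off,
                                   to = .data$to + off)),
    id = id
  )
}
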