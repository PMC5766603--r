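## Reaction database: long-format stoichiometry S_ij plus reversibility,
## transport flags, and optional pathway/organism annotation sets.

#' Build a reaction database from a stoichiometry table
#'
#' @param stoich tibble with columns `reaction`, `metabolite`, `coef`
#'   (negative = consumed); one row per (reaction, metabolite).
#' @param reversible named logical vector or tibble(`reaction`, `reversible`);
#'   defaults to all reversible.
#' @param transport optional character vector of transport reaction ids
#'   (excluded from rule extraction).
#' @param pathways,organisms optional named lists: reaction id -> character
#'   vector of annotation labels.
#' @return A `reaction_db`: list with `stoich` and `reactions` tibbles.
#' @export
reaction_db <- function(stoich, reversible = NULL, transport = character(0),
                        pathways = NULL, organisms = NULL) {
  stoich <- as_tibble(stoich)
  need <- c("reaction", "metabolite", "coef")
  if (!all(need %in% names(stoich))) {
    abort(paste0("stoichiometry table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(stoich$coef))) abort("non-numeric stoichiometric coefficient")
  zero <- which(stoich$coef == 0)
  if (length(zero) > 0L) {
    abort(paste0("zero stoichiometric coefficient in row(s) ",
                 paste(zero, collapse = ", ")))
  }
  dup <- stoich |> count(.data$reaction, .data$metabolite) |> filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate (reaction, metabolite) rows: ",
                 paste0(dup$reaction, "/", dup$metabolite, collapse = ", ")))
  }
  ids <- unique(stoich$reaction)
  sides <- stoich |>
    group_by(.data$reaction) |>
    summarise(has_sub = any(.data$coef < 0), has_prod = any(.data$coef > 0),
              .groups = "drop")
  onesided <- sides$reaction[!(sides$has_sub & sides$has_prod)]
  if (length(onesided) > 0L) {
    abort(paste0("reaction(s) without both a substrate and a product: ",
                 paste(onesided, collapse = ", ")))
  }
  if (is.null(reversible)) {
    rev <- stats::setNames(rep(TRUE, length(ids)), ids)
  } else if (is.data.frame(reversible)) {
    rev <- stats::setNames(as.logical(reversible$reversible), reversible$reaction)
  } else {
    rev <- reversible
  }
  reactions <- tibble(
    reaction = ids,
    reversible = unname(ifelse(is.na(rev[ids]), TRUE, rev[ids])),
    transport = ids %in% transport,
    pathways = lapply(ids, function(j) as.character(pathways[[j]] %||% character(0))),
    organisms = lapply(ids, function(j) as.character(organisms[[j]] %||% character(0)))
  )
  structure(list(stoich = stoich, reactions = reactions), class = "reaction_db")
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf("<reaction db: %d reactions, %d metabolites>\n",
              nrow(x$reactions), length(unique(x$stoich$metabolite))))
  invisible(x)
}

#' Metabolite ids appearing in a reaction database
#' @param db a `reaction_db`.
#' @return Character vector, sorted.
#' @export
db_metabolites <- function(db) sort(unique(db$stoich$metabolite))

.stoich_vector <- function(db, rxn_id) {
  rows <- db$stoich[db$stoich$reaction == rxn_id, ]
  if (nrow(rows) == 0L) abort(paste0("unknown reaction id: ", rxn_id))
  stats::setNames(rows$coef, rows$metabolite)
}

# dense stoichiometric matrix (metabolites x reactions)
.stoich_matrix <- function(db) {
  mets <- db_metabolites(db)
  rxns <- db$reactions$reaction
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  S[cbind(match(db$stoich$metabolite, mets), match(db$stoich$reaction, rxns))] <-
    db$stoich$coef
  S
}

#' Load a reaction database from a long-format TSV file
#'
#' Expected columns: `reaction`, `metabolite`, `coef`, `reversible`
#' (logical or 0/1), and optionally `transport`, `pathways`, `organisms`
#' (semicolon-separated label lists). One row per (reaction, metabolite) pair.
#'
#' @param path TSV file path.
#' @return A `reaction_db`.
#' @export
load_reactions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("reaction", "metabolite", "coef")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    abort(paste0("missing column(s) in ", path, ": ", paste(miss, collapse = ", ")))
  }
  coef <- suppressWarnings(as.numeric(tab$coef))
  if (any(is.na(coef))) {
    abort(paste0("non-numeric coefficient in row(s) ",
                 paste(which(is.na(coef)), collapse = ", "), " of ", path))
  }
  if (any(is.na(tab$metabolite) | tab$metabolite == "")) {
    abort(paste0("dangling metabolite id in row(s) ",
                 paste(which(is.na(tab$metabolite) | tab$metabolite == ""),
                       collapse = ", "), " of ", path))
  }
  stoich <- tibble(reaction = tab$reaction, metabolite = tab$metabolite,
                   coef = coef)
  rev <- NULL
  if ("reversible" %in% names(tab)) {
    per <- tab |>
      mutate(rv = .data$reversible %in% c("TRUE", "true", "1")) |>
      distinct(.data$reaction, .data$rv)
    rev <- stats::setNames(per$rv, per$reaction)
  }
  split_labels <- function(col) {
    if (!col %in% names(tab)) return(NULL)
    per <- tab |> distinct(.data$reaction, lab = .data[[col]])
    out <- lapply(per$lab, function(x) {
      if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    })
    stats::setNames(out, per$reaction)
  }
  transport <- character(0)
  if ("transport" %in% names(tab)) {
    per <- tab |>
      mutate(tr = .data$transport %in% c("TRUE", "true", "1")) |>
      distinct(.data$reaction, .data$tr)
    transport <- per$reaction[per$tr]
  }
  reaction_db(stoich, reversible = rev, transport = transport,
              pathways = split_labels("pathways"),
              organisms = split_labels("organisms"))
}

#' Write a reaction database to a long-format TSV file
#' @param db a `reaction_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(db, path) {
  joined <- db$stoich |>
    left_join(
      db$reactions |>
        mutate(pathways = purrr::map_chr(.data$pathways, paste, collapse = ";"),
               organisms = purrr::map_chr(.data$organisms, paste, collapse = ";")),
      by = "reaction"
    )
  readr::write_tsv(joined, path)
  invisible(path)
}

#' Audit the elemental balance of a reaction
#'
#' @param db a `reaction_db`.
#' @param rxn_id reaction to audit.
#' @param mols named list of `molecule` structures.
#' @return A tibble `element`, `residual` (products minus substrates, scaled
#'   by stoichiometry); all-zero residuals mean balanced. If a participant has
#'   no structure the result carries attribute `status = "unknown"` and lists
#'   the missing metabolites in attribute `missing`.
#' @export
check_reaction_balance <- function(db, rxn_id, mols) {
  st <- .stoich_vector(db, rxn_id)
  missing <- setdiff(names(st), names(mols))
  if (length(missing) > 0L) {
    out <- tibble(element = character(0), residual = numeric(0))
    attr(out, "status") <- "unknown"
    attr(out, "missing") <- missing
    return(out)
  }
  vec <- .elem_sum(lapply(names(st), function(m) .elem_vec(mols[[m]])), unname(st))
  out <- tibble(element = names(vec), residual = unname(vec)) |>
    arrange(.data$element)
  attr(out, "status") <- if (all(abs(out$residual) < 1e-9)) "balanced" else "unbalanced"
  out
}

#' Audit every reaction in a database
#' @inheritParams check_reaction_balance
#' @return A tibble `reaction`, `status`, `residuals` (list-column).
#' @export
check_db_balance <- function(db, mols) {
  purrr::map(db$reactions$reaction, function(j) {
    rep <- check_reaction_balance(db, j, mols)
    tibble(reaction = j, status = attr(rep, "status"), residuals = list(rep))
  }) |> bind_rows()
}

## ---- thermodynamics -------------------------------------------------------

#' Load a table of standard transformed formation energies
#'
#' Values are consumed as kcal/mol at pH 7.0 and ionic strength 0.1 M (the
#' convention of the component-contribution/eQuilibrator pipelines that
#' produce them); this package never computes formation energies itself.
#'
#' @param path TSV with columns `metabolite`, `dgf` (kcal/mol).
#' @return A named numeric vector (class `thermo_table`).
#' @export
load_thermo <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("metabolite", "dgf") %in% names(tab))) {
    abort("thermo table needs columns `metabolite` and `dgf`")
  }
  if (any(!is.finite(tab$dgf))) abort("non-finite formation energy")
  thermo_table(stats::setNames(tab$dgf, tab$metabolite))
}

#' Construct a thermodynamic table from a named vector
#' @param x named numeric vector: metabolite id -> formation energy (kcal/mol).
#' @return The vector with class `thermo_table`.
#' @export
thermo_table <- function(x) {
  if (any(!is.finite(x))) abort("non-finite formation energy")
  structure(as.numeric(x), names = names(x), class = "thermo_table")
}

#' Overall standard Gibbs energy change of a net conversion
#'
#' `sum_i dGf'(i) * vEX_i` over the exchange fluxes: negative means the
#' designed conversion is exergonic under standard transformed conditions.
#'
#' @param vex named numeric vector of exchange fluxes (positive = export).
#' @param thermo a `thermo_table`.
#' @return Overall delta G in kcal (per unit of designed conversion).
#' @export
overall_deltaG <- function(vex, thermo) {
  vex <- vex[vex != 0]
  if (length(vex) == 0L) return(0)
  missing <- setdiff(names(vex), names(thermo))
  if (length(missing) > 0L) {
    abort(paste0("no formation energy for exchanged metabolite(s): ",
                 paste(missing, collapse = ", ")))
  }
  sum(unclass(thermo)[names(vex)] * vex)
}
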