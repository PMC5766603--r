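#' @importFrom dplyr arrange mutate filter group_by summarise ungroup bind_rows
#'   left_join select distinct count n
NULL

## ---- prime registry -------------------------------------------------------

# The registry is the session-wide bijection between canonical moiety keys and
# prime numbers. A canonical key encodes an atom environment: at refinement
# level 0 it is (element, formal charge); at level k it is the atom's own
# level-(k-1) prime together with the sorted multiset of
# (bond order, neighbour level-(k-1) prime) pairs. Sorting the multiset makes
# the key independent of atom order; mapping each distinct key to a fresh
# prime keeps moiety identifiers compact and comparable across molecules.

.next_primes <- function(current_max, n_needed) {
  out <- integer(0)
  cand <- max(2L, current_max + 1L)
  while (length(out) < n_needed) {
    is_p <- TRUE
    if (cand < 2L) is_p <- FALSE
    else if (cand > 2L) {
      for (d in 2:floor(sqrt(cand))) {
        if (cand %% d == 0L) { is_p <- FALSE; break }
        if (d * d > cand) break
      }
    }
    if (is_p) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

#' Create a prime registry
#'
#' The registry assigns a unique prime to every distinct canonical moiety key
#' it sees, so that the same atom environment always maps to the same prime
#' within one session (and across sessions when the registry is serialized
#' alongside rule sets).
#'
#' @return An environment of class `prime_registry`.
#' @export
prime_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$map <- new.env(parent = emptyenv())   # key -> prime
  reg$keys <- character(0)                  # prime order -> key
  reg$primes <- integer(0)
  reg$center <- character(0)                # prime order -> center element
  class(reg) <- "prime_registry"
  reg
}

#' @export
print.prime_registry <- function(x, ...) {
  cat(sprintf("<prime registry: %d moiety keys>\n", length(x$keys)))
  invisible(x)
}

# Register a batch of keys. New keys are sorted lexicographically before
# primes are drawn, so assignment order within a batch is deterministic.
.register_keys <- function(reg, keys, centers) {
  uk <- !duplicated(keys)
  keys <- keys[uk]; centers <- centers[uk]
  new <- !vapply(keys, function(k) !is.null(reg$map[[k]]), logical(1))
  if (any(new)) {
    ord <- order(keys[new], method = "radix")
    nk <- keys[new][ord]; nc <- centers[new][ord]
    cur <- if (length(reg$primes)) reg$primes[length(reg$primes)] else 1L
    ps <- .next_primes(cur, length(nk))
    for (t in seq_along(nk)) {
      reg$map[[nk[t]]] <- ps[t]
    }
    reg$keys <- c(reg$keys, nk)
    reg$primes <- c(reg$primes, ps)
    reg$center <- c(reg$center, nc)
  }
  invisible(reg)
}

.lookup_primes <- function(reg, keys) {
  vapply(keys, function(k) reg$map[[k]], integer(1), USE.NAMES = FALSE)
}

# key -> center element for every registered prime
.registry_centers <- function(reg) {
  stats::setNames(reg$center, as.character(reg$primes))
}

# restore serialized entries (key, prime, center) into a registry; conflicts
# with existing assignments are an error because primes must stay a bijection
.restore_registry <- function(reg, keys, primes, centers) {
  for (t in seq_along(keys)) {
    ex <- reg$map[[keys[t]]]
    if (!is.null(ex)) {
      if (ex != primes[t]) {
        abort("registry conflict: key already bound to a different prime")
      }
    } else {
      if (primes[t] %in% reg$primes) {
        abort("registry conflict: prime already bound to a different key")
      }
      reg$map[[keys[t]]] <- as.integer(primes[t])
      reg$keys <- c(reg$keys, keys[t])
      reg$primes <- c(reg$primes, as.integer(primes[t]))
      reg$center <- c(reg$center, centers[t])
    }
  }
  invisible(reg)
}

## ---- canonical labels -----------------------------------------------------

#' Assign canonical moiety labels (primes) to every atom
#'
#' Labels are built by `lambda` rounds of neighbourhood refinement starting
#' from (element, formal charge): the level-0 key is the atom itself, and the
#' level-k key combines the atom's level-(k-1) prime with the sorted multiset
#' of (bond order, neighbour level-(k-1) prime) pairs. At moiety size
#' `lambda = 1` a label therefore encodes an atom with its incident bonds; at
#' `lambda = 2` the environment out to radius 2, and so on. Labels are
#' invariant under graph isomorphism: permuting atom indices permutes rows but
#' leaves the label multiset unchanged.
#'
#' @param mol a `molecule` (hydrogens must be explicit, as the parsers ensure).
#' @param lambda moiety size, one of 1, 2, 3.
#' @param registry a `prime_registry`; defaults to the session registry.
#' @return A tibble with one row per atom: `atom`, `element`, `key`, `prime`.
#' @export
atom_labels <- function(mol, lambda, registry = default_registry()) {
  if (!inherits(mol, "molecule")) abort("`mol` must be a molecule")
  if (!(length(lambda) == 1L && lambda %in% 1:3)) {
    abort("`lambda` must be 1, 2, or 3")
  }
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  el <- mol$atoms$element
  keys <- paste0("0|", el, "|", mol$atoms$charge)
  .register_keys(registry, keys, el)
  primes <- .lookup_primes(registry, keys)
  for (lev in seq_len(lambda)) {
    nk <- character(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      parts <- if (length(nb$nbr)) {
        sort(paste0(vapply(nb$order, format, character(1)), ":",
                    primes[nb$nbr]),
             method = "radix")
      } else character(0)
      nk[a] <- paste0(lev, "|", primes[a], "|", paste(parts, collapse = ","))
    }
    .register_keys(registry, nk, el)
    primes <- .lookup_primes(registry, nk)
    keys <- nk
  }
  tibble(atom = seq_len(n), element = el, key = keys, prime = primes)
}

# The package keeps one session registry so signatures are comparable across
# calls; pass an explicit registry to isolate work.
.pkg_env <- new.env(parent = emptyenv())

#' Session-wide default prime registry
#' @return The shared `prime_registry` (created on first use).
#' @export
default_registry <- function() {
  if (is.null(.pkg_env$registry)) .pkg_env$registry <- prime_registry()
  .pkg_env$registry
}

#' Reset the session prime registry
#' @return The fresh registry, invisibly.
#' @export
reset_registry <- function() {
  .pkg_env$registry <- prime_registry()
  invisible(.pkg_env$registry)
}

## ---- molecular signatures -------------------------------------------------

#' Molecular signature: moiety counts at size lambda
#'
#' The signature of metabolite i is the sparse count vector over
#' moieties m present in the molecule at moiety size lambda:
#' `counts[m]` = number of atoms whose canonical label is m. The total count
#' equals the atom count at every lambda (one moiety per center atom), and the
#' signature is additive over disconnected components.
#'
#' @inheritParams atom_labels
#' @return A tibble with columns `moiety` (prime), `key`, `count`, sorted by
#'   `moiety`; attributes `id` and `lambda`.
#' @export
mol_signature <- function(mol, lambda, registry = default_registry()) {
  lab <- atom_labels(mol, lambda, registry)
  sig <- lab |>
    count(.data$prime, .data$key, name = "count") |>
    arrange(.data$prime) |>
    dplyr::rename(moiety = "prime")
  attr(sig, "id") <- mol$id
  attr(sig, "lambda") <- lambda
  sig
}

#' Signatures for a set of metabolites
#'
#' @param mols named list of `molecule` objects (names are metabolite ids).
#' @inheritParams atom_labels
#' @return A tibble `metabolite`, `moiety`, `key`, `count` of class
#'   `signature_index` with attribute `lambda`.
#' @export
signature_index <- function(mols, lambda, registry = default_registry()) {
  ids <- names(mols) %||% purrr::map_chr(mols, "id")
  sigs <- purrr::map2(mols, ids, function(m, id) {
    s <- mol_signature(m, lambda, registry)
    mutate(s, metabolite = id, .before = 1)
  })
  out <- bind_rows(sigs)
  attr(out, "lambda") <- lambda
  attr(out, "registry") <- registry
  class(out) <- c("signature_index", class(out))
  out
}

# per-metabolite element counts recovered from a signature index via the
# registry's center-element record (one atom per moiety instance)
.sig_elements <- function(sigs, registry) {
  centers <- .registry_centers(registry)
  sigs |>
    mutate(element = unname(centers[as.character(.data$moiety)])) |>
    group_by(.data$metabolite, .data$element) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

## ---- reaction rules -------------------------------------------------------

#' Derive the reaction rule for one reaction
#'
#' The rule is the net moiety-change vector
#' `changes[m] = sum_i S_ij * counts[m, i]` over all participants (cofactors
#' included), with zero entries dropped. Rules derived from elementally
#' balanced reactions are elementally balanced by construction; unbalanced
#' reactions are rejected because they would generate unbalanced rules.
#'
#' @param stoich named numeric vector of stoichiometric coefficients
#'   (negative = consumed), names are metabolite ids.
#' @param sigs a `signature_index` covering every participant.
#' @param registry registry used to build `sigs`.
#' @return A tibble `moiety`, `key`, `change` (class `reaction_rule_changes`)
#'   with attribute `lambda`; the identity reaction yields zero rows.
#' @export
derive_rule <- function(stoich, sigs, registry = default_registry()) {
  mets <- names(stoich)
  missing <- setdiff(mets, unique(sigs$metabolite))
  if (length(missing) > 0L) {
    abort(paste0("no signature for metabolite(s): ",
                 paste(missing, collapse = ", ")))
  }
  part <- sigs |> filter(.data$metabolite %in% mets)
  # element balance audit from the signatures themselves
  elem <- .sig_elements(part, registry) |>
    mutate(coef = stoich[.data$metabolite]) |>
    group_by(.data$element) |>
    summarise(residual = sum(.data$coef * .data$count), .groups = "drop") |>
    filter(abs(.data$residual) > 1e-9)
  if (nrow(elem) > 0L) {
    abort(paste0("elementally unbalanced reaction (residuals: ",
                 paste0(elem$element, ":", elem$residual, collapse = ", "),
                 "); unbalanced reactions must not generate rules"))
  }
  chg <- part |>
    mutate(coef = stoich[.data$metabolite]) |>
    group_by(.data$moiety, .data$key) |>
    summarise(change = sum(.data$coef * .data$count), .groups = "drop") |>
    filter(abs(.data$change) > 1e-9) |>
    mutate(change = as.integer(round(.data$change))) |>
    arrange(.data$moiety)
  attr(chg, "lambda") <- attr(sigs, "lambda")
  class(chg) <- c("reaction_rule_changes", class(chg))
  chg
}

# canonical fingerprint of a change map, used for deduplication and for
# order-independent rule ids
.rule_fingerprint <- function(chg) {
  if (nrow(chg) == 0L) return("<identity>")
  paste0(chg$moiety, ":", chg$change, collapse = ";")
}

#' Extract the unique rule set from a reaction database
#'
#' Derives the moiety-change rule of every (non-transport) reaction at size
#' `lambda` and removes repetitions: two reactions map to the same rule
#' exactly when their change maps are identical. Rule ids are assigned from
#' the sorted canonical fingerprints, so shuffling the database yields the
#' same rule set and the same ids. Per-reaction failures (missing structures,
#' unbalanced stoichiometry) are collected in the `rejected` table and the
#' run continues.
#'
#' @param db a `reaction_db` (see [load_reactions()]).
#' @param mols named list of `molecule` structures covering the metabolites.
#' @param lambda moiety size (1, 2, or 3). Rules of different sizes are never
#'   mixed in one set.
#' @param registry a `prime_registry`.
#' @return A `rule_set`: list with `lambda`, `rules` (tibble `rule_id`,
#'   `moiety`, `key`, `change`), `info` (tibble `rule_id`, `reversible`,
#'   `member_reactions` list-column, `pathways`, `organisms`), `map` (tibble
#'   `reaction`, `rule_id`), `rejected`, and the registry.
#' @export
extract_rules <- function(db, mols, lambda, registry = default_registry()) {
  stopifnot(inherits(db, "reaction_db"))
  sigs <- signature_index(mols, lambda, registry)
  rxns <- db$reactions
  rxns <- rxns[!rxns$transport, , drop = FALSE]
  derived <- list(); rejected <- list()
  for (j in rxns$reaction) {
    st <- .stoich_vector(db, j)
    res <- tryCatch(derive_rule(st, sigs, registry), error = function(e) e)
    if (inherits(res, "error")) {
      rejected[[j]] <- tibble(reaction = j, reason = conditionMessage(res))
    } else {
      derived[[j]] <- res
    }
  }
  fps <- purrr::map_chr(derived, .rule_fingerprint)
  ufp <- sort(unique(fps), method = "radix")
  rule_ids <- stats::setNames(paste0("R", seq_along(ufp)), ufp)
  map <- tibble(reaction = names(fps), rule_id = unname(rule_ids[fps]))
  rules <- purrr::imap(derived, function(chg, j) {
    mutate(chg, rule_id = unname(rule_ids[[.rule_fingerprint(chg)]]), .before = 1)
  }) |>
    bind_rows() |>
    distinct(.data$rule_id, .data$moiety, .data$key, .data$change) |>
    arrange(.data$rule_id, .data$moiety)
  ann <- rxns |> select(dplyr::any_of(c("reaction", "pathways", "organisms")))
  info <- map |>
    left_join(ann, by = "reaction") |>
    group_by(.data$rule_id) |>
    summarise(
      member_reactions = list(sort(.data$reaction)),
      pathways = list(sort(unique(unlist(.data$pathways)))),
      organisms = list(sort(unique(unlist(.data$organisms)))),
      .groups = "drop"
    ) |>
    # every rule is assumed reversible; direction pins are a design-time choice
    mutate(reversible = TRUE)
  structure(
    list(lambda = lambda, rules = rules, info = info, map = map,
         rejected = bind_rows(rejected), registry = registry),
    class = "rule_set"
  )
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule set: lambda=%d, %d unique rules from %d reactions (%d rejected)>\n",
              x$lambda, nrow(x$info), nrow(x$map), nrow(x$rejected)))
  invisible(x)
}

#' Number of unique rules in a rule set
#' @param rs a `rule_set`.
#' @return Integer count.
#' @export
n_rules <- function(rs) nrow(rs$info)

#' Per-element balance of every rule in a set
#'
#' Maps each moiety to its center atom's element and sums `change x 1` per
#' element: a rule extracted from balanced reactions must have all residuals
#' zero.
#'
#' @param rs a `rule_set`.
#' @return A tibble `rule_id`, `element`, `residual`.
#' @export
rule_element_balance <- function(rs) {
  centers <- .registry_centers(rs$registry)
  rs$rules |>
    mutate(element = unname(centers[as.character(.data$moiety)])) |>
    group_by(.data$rule_id, .data$element) |>
    summarise(residual = sum(.data$change), .groups = "drop")
}

#' @export
tidy.rule_set <- function(x, ...) {
  x$rules |>
    left_join(select(x$info, "rule_id", "reversible"), by = "rule_id") |>
    mutate(lambda = x$lambda, .before = 1)
}

#' @export
glance.rule_set <- function(x, ...) {
  tibble(lambda = x$lambda, n_rules = nrow(x$info),
         n_reactions = nrow(x$map), n_rejected = nrow(x$rejected))
}

## ---- serialization --------------------------------------------------------

#' Write a rule set to JSON
#'
#' The registry entries referenced by the rules are serialized alongside the
#' change maps so signatures remain comparable across runs.
#'
#' @param rs a `rule_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rule_set <- function(rs, path) {
  # the whole registry is serialized: moiety keys at size lambda embed the
  # primes of lower refinement levels, so re-signing new molecules against a
  # restored registry needs every level's key -> prime binding
  reg <- rs$registry
  keep <- rep(TRUE, length(reg$primes))
  payload <- list(
    lambda = rs$lambda,
    rules = purrr::map(split(rs$rules, rs$rules$rule_id), function(d) {
      list(moiety = d$moiety, key = d$key, change = d$change)
    }),
    info = purrr::map(split(rs$info, rs$info$rule_id), function(d) {
      list(reversible = d$reversible,
           member_reactions = d$member_reactions[[1]],
           pathways = d$pathways[[1]], organisms = d$organisms[[1]])
    }),
    map = rs$map,
    registry = list(key = reg$keys[keep], prime = reg$primes[keep],
                    center = reg$center[keep])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path file written by [write_rule_set()].
#' @param registry registry to merge the serialized entries into.
#' @return A `rule_set`.
#' @export
read_rule_set <- function(path, registry = default_registry()) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  .restore_registry(registry, p$registry$key, p$registry$prime, p$registry$center)
  rules <- purrr::imap(p$rules, function(r, id) {
    tibble(rule_id = id, moiety = as.integer(r$moiety), key = r$key,
           change = as.integer(r$change))
  }) |> bind_rows() |> arrange(.data$rule_id, .data$moiety)
  info <- purrr::imap(p$info, function(r, id) {
    tibble(rule_id = id, reversible = isTRUE(r$reversible),
           member_reactions = list(r$member_reactions %||% character(0)),
           pathways = list(r$pathways %||% character(0)),
           organisms = list(r$organisms %||% character(0)))
  }) |> bind_rows()
  structure(
    list(lambda = as.integer(p$lambda), rules = rules, info = info,
         map = as_tibble(p$map), rejected = tibble(), registry = registry),
    class = "rule_set"
  )
}
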