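## Rule instantiation: matching a reaction rule onto concrete substrate
## structures and proposing product structures by bounded graph-edit search,
## verified at signature level. Pathway design never depends on this module;
## instantiation is post-processing of designed routes.

# change map of one rule, optionally negated for reverse application
.rule_changes <- function(rs, rule_id, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  chg <- rs$rules[rs$rules$rule_id == rule_id, c("moiety", "key", "change")]
  if (nrow(chg) == 0L && !rule_id %in% rs$info$rule_id) {
    abort(paste0("unknown rule id: ", rule_id))
  }
  if (direction == "reverse") chg$change <- -chg$change
  chg
}

# disjoint union of a list of molecules, remembering atom provenance
.combine_substrates <- function(substrates) {
  if (inherits(substrates, "molecule")) substrates <- list(substrates)
  combined <- substrates[[1]]
  offsets <- 0L
  if (length(substrates) > 1L) {
    for (k in 2:length(substrates)) {
      offsets <- c(offsets, n_atoms(combined))
      combined <- .mol_union(combined, substrates[[k]], id = "substrates")
    }
  }
  combined$id <- "substrates"
  combined
}

#' Find candidate reaction centers for a rule on substrates
#'
#' A center is a set of atoms that covers every moiety consumed by the rule
#' (negative change entries, at the required multiplicities). When several
#' atom assignments are possible, only those maximizing the number of bonds
#' among the chosen atoms are returned — the consumed moieties of a genuine
#' reaction center are locally connected through the substrate, up to
#' co-substrates which stay as separate components. Centers are returned in
#' deterministic order (sorted atom index lists).
#'
#' @param rs a `rule_set`.
#' @param rule_id rule to match.
#' @param substrates a `molecule` or list of molecules, signed at the rule's
#'   moiety size.
#' @param direction `"forward"` consumes the rule's negative moieties;
#'   `"reverse"` its positive ones.
#' @param max_tuples cap on examined atom assignments.
#' @return A tibble `center` (id), `atoms` (list-column of atom indices into
#'   the combined substrate graph), `adjacency`; zero rows when a required
#'   moiety is absent.
#' @export
match_sites <- function(rs, rule_id, substrates,
                        direction = c("forward", "reverse"),
                        max_tuples = 5000L) {
  direction <- match.arg(direction)
  chg <- .rule_changes(rs, rule_id, direction)
  need <- chg[chg$change < 0L, ]
  combined <- .combine_substrates(substrates)
  labs <- atom_labels(combined, rs$lambda, rs$registry)
  empty <- tibble(center = integer(0), atoms = list(), adjacency = integer(0))
  if (nrow(need) == 0L) return(empty)

  slots <- list()
  for (r in seq_len(nrow(need))) {
    atoms_r <- labs$atom[labs$prime == need$moiety[r]]
    mult <- abs(need$change[r])
    if (length(atoms_r) < mult) return(empty)
    combos <- if (length(atoms_r) == mult) {
      list(atoms_r)
    } else {
      utils::combn(atoms_r, mult, simplify = FALSE)
    }
    slots[[length(slots) + 1L]] <- combos
  }
  total <- prod(vapply(slots, length, numeric(1)))
  if (total > max_tuples) {
    warn(sprintf("site matching truncated: %.0f candidate assignments, keeping %d",
                 total, max_tuples))
  }
  sizes <- vapply(slots, length, integer(1))
  base <- c(1, cumprod(sizes))[seq_along(sizes)]
  n_take <- min(total, max_tuples)
  bonded <- matrix(FALSE, n_atoms(combined), n_atoms(combined))
  bonded[cbind(combined$bonds$from, combined$bonds$to)] <- TRUE
  bonded[cbind(combined$bonds$to, combined$bonds$from)] <- TRUE
  tuples <- vector("list", n_take)
  adjc <- integer(n_take)
  for (t in seq_len(n_take)) {
    pickidx <- ((t - 1L) %/% base) %% sizes + 1L
    atoms <- sort(unique(unlist(purrr::map2(slots, pickidx, ~ .x[[.y]]))))
    tuples[[t]] <- atoms
    adjc[t] <- sum(bonded[atoms, atoms]) / 2L
  }
  keyed <- vapply(tuples, paste, character(1), collapse = ",")
  keep <- !duplicated(keyed)
  tuples <- tuples[keep]; adjc <- adjc[keep]
  best <- adjc == max(adjc)
  tuples <- tuples[best]; adjc <- adjc[best]
  ord <- order(vapply(tuples, paste, character(1), collapse = ","),
               method = "radix")
  tibble(center = seq_along(ord), atoms = tuples[ord], adjacency = adjc[ord])
}

#' Instantiate a rule at a reaction center
#'
#' Searches bounded graph edits (bond order changes of one unit on atom pairs
#' touching the center, default at most `max_edits` of them) for product
#' structures whose recomputed signature difference equals the rule's change
#' map exactly; candidates violating allowed valences are pruned during the
#' search, and surviving candidates are deduplicated by their canonical
#' labels at moiety size 3 and ranked by fewest edits. At small moiety sizes
#' several residual-zero products are expected (the rule underdetermines the
#' structure); all are returned.
#'
#' @inheritParams match_sites
#' @param center integer vector of atom indices (one row's `atoms` from
#'   [match_sites()]), or `NULL` for a rule with no consumed moieties
#'   (identity).
#' @param max_edits edit budget (bond order unit changes).
#' @param max_products stop after this many distinct residual-zero products.
#' @return A `rule_application`: list with `rule_id`, `direction`, `center`,
#'   `products` (list; each element a list of component molecules),
#'   `n_edits`, `residual_ok`, and `status` (`"ok"` or
#'   `"unrealizable at this center"`).
#' @export
apply_rule <- function(rs, rule_id, substrates, center = NULL,
                       direction = c("forward", "reverse"),
                       max_edits = 4L, max_products = 10L) {
  direction <- match.arg(direction)
  chg <- .rule_changes(rs, rule_id, direction)
  combined <- .combine_substrates(substrates)
  reg <- rs$registry
  lam <- rs$lambda

  base_sig <- mol_signature(combined, lam, reg)
  target <- .sig_plus_changes(base_sig, chg)
  if (is.null(target)) {
    return(.rule_application(rule_id, direction, center, list(), integer(0),
                             "unrealizable at this center"))
  }
  if (nrow(chg) == 0L) {
    # identity rule: substrates unchanged
    prods <- split_components(combined, id_prefix = "product")
    return(.rule_application(rule_id, direction, center, list(prods), 0L, "ok"))
  }
  if (is.null(center)) abort("a reaction center is required for a non-identity rule")

  n <- n_atoms(combined)
  adj <- .adjacency(combined)
  affected <- sort(unique(c(center,
                            unlist(lapply(center, function(a) adj[[a]]$nbr)))))
  # current bond orders as a dense lookup over affected pairs
  ord_of <- function(i, j) {
    b <- combined$bonds
    hit <- which((b$from == i & b$to == j) | (b$from == j & b$to == i))
    if (length(hit) == 0L) 0 else b$order[hit[1]]
  }
  pairs <- list()
  for (i in center) {
    for (j in affected) {
      if (j <= i && j %in% center) next  # avoid double-listing center pairs
      if (j == i) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  pairs <- unique(lapply(pairs, function(p) sort(p)))
  cur <- vapply(pairs, function(p) ord_of(p[1], p[2]), numeric(1))
  # unit bond-order moves; aromatic bonds are left untouched (rule edits act
  # on the sigma/pi framework, not on delocalized systems)
  moves <- list()
  for (k in seq_along(pairs)) {
    if (cur[k] == AROMATIC) next
    if (cur[k] < 3) moves[[length(moves) + 1L]] <- c(pairs[[k]], +1, k)
    if (cur[k] > 0) moves[[length(moves) + 1L]] <- c(pairs[[k]], -1, k)
  }
  nm <- length(moves)
  if (nm == 0L) {
    return(.rule_application(rule_id, direction, center, list(), integer(0),
                             "unrealizable at this center"))
  }

  el <- combined$atoms$element
  qv <- combined$atoms$charge
  osum <- numeric(n)
  for (k in seq_len(nrow(combined$bonds))) {
    b <- combined$bonds
    osum[b$from[k]] <- osum[b$from[k]] + b$order[k]
    osum[b$to[k]] <- osum[b$to[k]] + b$order[k]
  }
  valence_ok <- function(a, s) {
    v <- .VALENCES[[el[a]]]
    if (is.null(v)) return(TRUE)
    # charged atoms keep their parsed valence: require unchanged sum
    if (qv[a] != 0L) return(abs(s - osum[a]) < 1e-9)
    any(abs(v - s) < 1e-9)
  }
  maxval <- vapply(seq_len(n), function(a) {
    v <- .VALENCES[[el[a]]]
    if (is.null(v)) Inf else max(v)
  }, numeric(1))

  target_fp <- paste0(target$moiety, ":", target$count, collapse = ";")
  found <- list(); found_edits <- integer(0); found_fp <- character(0)

  check_candidate <- function(deltas) {
    b <- combined$bonds
    m2 <- combined
    for (k in which(deltas != 0)) {
      p <- pairs[[k]]
      hit <- which((b$from == p[1] & b$to == p[2]) |
                     (b$from == p[2] & b$to == p[1]))
      if (length(hit) > 0L) {
        m2$bonds$order[hit[1]] <- m2$bonds$order[hit[1]] + deltas[k]
      } else {
        m2$bonds <- dplyr::bind_rows(m2$bonds,
                                     tibble(from = p[1], to = p[2],
                                            order = deltas[k]))
      }
    }
    m2$bonds <- m2$bonds[m2$bonds$order > 0, ]
    sig <- mol_signature(m2, lam, reg)
    if (paste0(sig$moiety, ":", sig$count, collapse = ";") != target_fp) {
      return(NULL)
    }
    m2
  }

  deltas <- numeric(length(pairs))
  sums <- osum
  recurse <- function(start, depth) {
    if (length(found) >= max_products) return()
    if (depth > 0L) {
      bad <- vapply(affected, function(a) !valence_ok(a, sums[a]), logical(1))
      if (!any(bad)) {
        m2 <- check_candidate(deltas)
        if (!is.null(m2)) {
          fp <- paste(sort(atom_labels(m2, 3, reg)$key), collapse = "\r")
          if (!fp %in% found_fp) {
            found[[length(found) + 1L]] <<-
              split_components(m2, id_prefix = "product")
            found_edits[length(found_edits) + 1L] <<- depth
            found_fp[length(found_fp) + 1L] <<- fp
          }
        }
      }
    }
    if (depth == max_edits || start > nm) return()
    for (mi in start:nm) {
      if (length(found) >= max_products) return()
      mv <- moves[[mi]]
      k <- mv[4]
      if (deltas[k] != 0) next
      newo <- cur[k] + mv[3]
      if (newo < 0 || newo > 3) next
      a1 <- mv[1]; a2 <- mv[2]
      # later moves can lower a sum by at most one each, so allow transient
      # overshoot up to the remaining edit budget
      slack <- max_edits - depth - 1L
      if (sums[a1] + mv[3] > maxval[a1] + slack ||
          sums[a2] + mv[3] > maxval[a2] + slack) next
      deltas[k] <<- mv[3]
      sums[a1] <<- sums[a1] + mv[3]; sums[a2] <<- sums[a2] + mv[3]
      recurse(mi + 1L, depth + 1L)
      deltas[k] <<- 0
      sums[a1] <<- sums[a1] - mv[3]; sums[a2] <<- sums[a2] - mv[3]
    }
  }
  recurse(1L, 0L)

  if (length(found) == 0L) {
    return(.rule_application(rule_id, direction, center, list(), integer(0),
                             "unrealizable at this center"))
  }
  ord <- order(found_edits)
  .rule_application(rule_id, direction, center, found[ord], found_edits[ord], "ok")
}

.sig_plus_changes <- function(sig, chg) {
  merged <- dplyr::full_join(
    tibble(moiety = sig$moiety, count = sig$count),
    tibble(moiety = chg$moiety, change = chg$change),
    by = "moiety"
  ) |>
    mutate(count = dplyr::coalesce(.data$count, 0L) +
             dplyr::coalesce(.data$change, 0L)) |>
    filter(.data$count != 0L) |>
    arrange(.data$moiety)
  if (any(merged$count < 0L)) return(NULL)  # rule consumes absent moieties
  merged[, c("moiety", "count")]
}

.rule_application <- function(rule_id, direction, center, products, n_edits,
                              status) {
  structure(
    list(rule_id = rule_id, direction = direction, center = center,
         products = products, n_edits = n_edits,
         residual_ok = length(products) > 0L, status = status),
    class = "rule_application"
  )
}

#' @export
print.rule_application <- function(x, ...) {
  cat(sprintf("<rule application %s (%s): %d candidate product set(s), %s>\n",
              x$rule_id, x$direction, length(x$products), x$status))
  invisible(x)
}

#' Apply a rule at every matched center
#'
#' Convenience wrapper chaining [match_sites()] and [apply_rule()]; candidate
#' product sets from all centers are pooled and deduplicated by canonical
#' labels.
#'
#' @inheritParams apply_rule
#' @return A list of `rule_application` objects, one per center.
#' @export
apply_rule_everywhere <- function(rs, rule_id, substrates,
                                  direction = c("forward", "reverse"),
                                  max_edits = 4L, max_products = 10L) {
  direction <- match.arg(direction)
  sites <- match_sites(rs, rule_id, substrates, direction)
  purrr::map(sites$atoms, function(ctr) {
    apply_rule(rs, rule_id, substrates, center = ctr, direction = direction,
               max_edits = max_edits, max_products = max_products)
  })
}
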