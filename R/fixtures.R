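## Self-contained fixtures: the two-decarboxylase toy system and seeded
## synthetic networks with planted, brute-force-certified routes.

#' The two-decarboxylase toy system
#'
#' Two reactions — 2-hydroxyisophthalate decarboxylase (`2HIPD`:
#' 2hipa -> sal + CO2) and salicylate decarboxylase (`SLD`:
#' sal -> phnl + CO2) — over four metabolites (2-hydroxyisophthalate,
#' salicylate, CO2, phenol), drawn as neutral acids. Rule extraction on this
#' database yields one unique rule at moiety size 1 (the two decarboxylations
#' share their radius-1 chemistry) and two at size 2. Formation energies are
#' synthetic but ordered so both decarboxylations are exergonic.
#'
#' @param charged if `TRUE`, the carboxylates are returned deprotonated
#'   (formal charge -1 on one carboxyl oxygen), for charge-sensitive labeling
#'   tests.
#' @return List with `db` (a `reaction_db`), `mols` (named molecule list) and
#'   `thermo` (a `thermo_table`, kcal/mol).
#' @export
toy_decarboxylase_db <- function(charged = FALSE) {
  smiles <- if (charged) {
    c(`2hipa` = "[O-]C(=O)c1cccc(C([O-])=O)c1O",
      sal = "[O-]C(=O)c1ccccc1O", phnl = "Oc1ccccc1", co2 = "O=C=O")
  } else {
    c(`2hipa` = "OC(=O)c1cccc(C(O)=O)c1O",
      sal = "OC(=O)c1ccccc1O", phnl = "Oc1ccccc1", co2 = "O=C=O")
  }
  mols <- purrr::imap(as.list(smiles), function(s, id) .parse_smiles(s, id = id))
  st <- tibble(
    reaction = c("2HIPD", "2HIPD", "2HIPD", "SLD", "SLD", "SLD"),
    metabolite = c("2hipa", "sal", "co2", "sal", "phnl", "co2"),
    coef = c(-1, 1, 1, -1, 1, 1)
  )
  db <- reaction_db(st,
                    pathways = list(`2HIPD` = "toy_decarboxylation",
                                    SLD = "toy_decarboxylation"),
                    organisms = list(`2HIPD` = "toy_genus", SLD = "toy_genus"))
  thermo <- thermo_table(c(`2hipa` = -180, sal = -140, phnl = -95, co2 = -94))
  list(db = db, mols = mols, thermo = thermo)
}

#' Design problem for the toy conversion 2hipa -> phnl
#'
#' One mol of 2-hydroxyisophthalate is taken up, one mol of phenol exported,
#' CO2 freely exchangeable. At moiety size 2 with the step cap at the known
#' route length (2), enumeration returns the four direct designs that blend
#' the two known reactions with the two extracted rules.
#'
#' @param lambda moiety size (default 2).
#' @param ... overrides passed to [design_problem()].
#' @return A `design_problem`.
#' @export
toy_design <- function(lambda = 2, ...) {
  args <- list(
    source = "2hipa", target = "phnl",
    exchange = tibble(metabolite = c("2hipa", "phnl", "co2"),
                      lb = c(-1, 1, -10), ub = c(-1, 1, 10)),
    lambda = lambda, objective = "min_total_steps", max_steps = 2
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(design_problem, args)
}

#' Design problem for the reverse (carboxylation) toy conversion
#'
#' Phenol + CO2 -> salicylate has a positive overall standard Gibbs energy
#' under the toy formation energies (+49 kcal), so the design is rejected
#' while the thermodynamic row is active and admitted when it is disabled —
#' useful for inspecting thermodynamically infeasible candidates.
#'
#' @inheritParams toy_design
#' @return A `design_problem`.
#' @export
toy_design_uphill <- function(lambda = 2, ...) {
  args <- list(
    source = "phnl", target = "sal",
    exchange = tibble(metabolite = c("phnl", "sal", "co2"),
                      lb = c(-1, 1, -10), ub = c(-1, 1, 10)),
    lambda = lambda, objective = "min_total_steps", max_steps = 2
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(design_problem, args)
}

## ---- planted networks -----------------------------------------------------

# linear heteroatom chain H-X-CH2-X-CH2-...-X-H as SMILES
.chain_smiles <- function(n, het = c("O", "N")) {
  het <- match.arg(het)
  paste0(het, strrep(paste0("C", het), n))
}

.planted_mols <- function(oxy_lengths, aza_lengths) {
  mols <- list()
  for (n in oxy_lengths) {
    id <- paste0("oxy", n)
    mols[[id]] <- .parse_smiles(.chain_smiles(n, "O"), id = id)
  }
  for (n in aza_lengths) {
    id <- paste0("aza", n)
    mols[[id]] <- .parse_smiles(.chain_smiles(n, "N"), id = id)
  }
  mols$fald <- .parse_smiles("C=O", id = "fald")     # formaldehyde unit
  mols$mimn <- .parse_smiles("C=N", id = "mimn")     # methanimine unit
  mols$h2o <- .parse_smiles("O", id = "h2o")
  mols
}

#' Generate a synthetic reaction network with a planted route
#'
#' Builds a family of heteroatom-chain metabolites (formaldehyde-unit
#' oligomers and their aza analogues), plants a source-to-target route of
#' exactly `route_len` single-unit cleavage steps, and surrounds it with
#' random balanced decoy reactions (condensations, aza cleavages, random
#' reversibility). Two extra cleavage reactions are returned separately as
#' rule donors. At generation time the planted optimum is certified by
#' exhaustive integer enumeration over the known network at the default
#' [planted_design()] bounds: decoy draws that shorten the route below
#' `route_len` are rejected and redrawn.
#'
#' @param n_mets target number of metabolites (>= route_len + 1).
#' @param n_rxns number of known reactions (>= route_len).
#' @param route_len number of planted steps (0 = source equals target).
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param certify verify the planted optimum by brute force (default TRUE).
#' @return A `planted_network`: list with `db`, `rule_db` (donor reactions),
#'   `mols`, `thermo`, `route` (ordered step ids), `source`, `target`,
#'   `seed`.
#' @export
planted_network <- function(n_mets = 6, n_rxns = 8, route_len = 3, seed = 1,
                            certify = TRUE) {
  if (route_len > n_rxns) abort("route_len must not exceed n_rxns")
  if (n_mets < route_len + 1) abort("need n_mets >= route_len + 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  s <- route_len + 1L          # source chain length
  max_len <- s + 1L
  oxy_lengths <- seq_len(max_len)
  n_aza <- max(0L, min(4L, n_mets - (max_len + 3L)))
  aza_lengths <- seq_len(max(n_aza, 2L))
  mols <- .planted_mols(oxy_lengths, aza_lengths)
  source <- paste0("oxy", s)
  target <- "oxy1"

  cleave_oxy <- function(k) {
    tibble(metabolite = c(paste0("oxy", k), paste0("oxy", k - 1), "fald"),
           coef = c(-1, 1, 1))
  }
  cleave_aza <- function(k) {
    tibble(metabolite = c(paste0("aza", k), paste0("aza", k - 1), "mimn"),
           coef = c(-1, 1, 1))
  }
  condense_oxy <- function(a, b) {
    out <- tibble(metabolite = c(paste0("oxy", a), paste0("oxy", b),
                                 paste0("oxy", a + b), "h2o"),
                  coef = c(-1, -1, 1, 1))
    if (a == b) out <- out[-2, ] |> mutate(coef = replace(.data$coef, 1, -2))
    out
  }

  pick <- function(x) x[sample.int(length(x), 1L)]  # sample() misreads scalars

  route_ids <- if (route_len > 0) paste0("step", seq_len(route_len)) else character(0)
  route_st <- purrr::map2(rev(seq_len(s))[seq_len(route_len)], route_ids,
                          function(k, id) mutate(cleave_oxy(k), reaction = id))

  draw_decoys <- function(n_decoys) {
    out <- list()
    for (d in seq_len(n_decoys)) {
      kind <- sample(c("condense", "aza"), 1)
      st <- if (kind == "condense") {
        a <- pick(seq_len(max_len - 1))
        b <- pick(seq_len(max_len - a))
        condense_oxy(a, b)
      } else {
        cleave_aza(pick(setdiff(aza_lengths, 1)))
      }
      out[[d]] <- mutate(st, reaction = paste0("decoy", d))
    }
    out
  }

  build_db <- function(decoys) {
    st <- bind_rows(c(route_st, decoys)) |>
      select("reaction", "metabolite", "coef")
    ids <- unique(st$reaction)
    rev_flags <- stats::setNames(
      c(rep(TRUE, length(route_ids)),
        sample(c(TRUE, FALSE), length(ids) - length(route_ids), replace = TRUE)),
      ids)
    reaction_db(st, reversible = rev_flags)
  }

  thermo <- thermo_table(c(
    stats::setNames(-40 - 25 * oxy_lengths, paste0("oxy", oxy_lengths)),
    stats::setNames(-30 - 20 * aza_lengths, paste0("aza", aza_lengths)),
    fald = -30, mimn = -20, h2o = -56
  ))

  n_decoys <- n_rxns - route_len
  db <- NULL
  for (try in seq_len(20L)) {
    cand <- build_db(draw_decoys(n_decoys))
    if (!certify || route_len == 0) { db <- cand; break }
    prob <- .planted_problem(source, target, route_len)
    reg <- prime_registry()
    sigs <- signature_index(mols, 1, reg)
    model <- build_design_model(prob, cand, NULL, sigs, thermo)
    designs <- enumerate_designs_bruteforce(model)
    if (nrow(designs) > 0L && min(designs$step_count) == route_len) {
      db <- cand
      break
    }
  }
  if (is.null(db)) {
    abort("could not plant a network whose shortest route is route_len (after 20 retries)")
  }

  # rule donors: one usable cleavage in the oligomer family, one dead-end aza
  donor_k <- pick(2:max_len)
  donor_st <- bind_rows(
    mutate(cleave_oxy(donor_k), reaction = "donor_oxy"),
    mutate(cleave_aza(max(aza_lengths)), reaction = "donor_aza")
  ) |> select("reaction", "metabolite", "coef")
  rule_db <- reaction_db(donor_st)

  structure(
    list(db = db, rule_db = rule_db, mols = mols, thermo = thermo,
         route = route_ids, source = source, target = target, seed = seed,
         route_len = route_len),
    class = "planted_network"
  )
}

.planted_problem <- function(source, target, route_len, ...) {
  if (identical(source, target)) {
    ex <- tibble(metabolite = c(source, "fald"), lb = c(-1, -4), ub = c(1, 4))
  } else {
    ex <- tibble(metabolite = c(source, target, "fald"),
                 lb = c(-1, 1, -4), ub = c(-1, 1, 4))
  }
  # Unit flux bounds for the planted optimum: the oligomer family's
  # signatures are affine in chain length, so at larger bounds a single
  # cleavage step run at flux 2 legitimately stands in for two distinct
  # steps at the moiety level. With |flux| <= 1 the planted route length is
  # the certified optimum. Pass flux_bound = 2 for feasibility-set studies.
  args <- list(source = source, target = target, exchange = ex, lambda = 1,
               objective = "min_total_steps", flux_bound = 1L,
               use_thermo = route_len > 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(design_problem, args)
}

#' Design problem matching a planted network
#'
#' Fixes uptake of the planted source and export of the target at one mol,
#' leaves the formaldehyde unit freely exchangeable within its bounds, works
#' at moiety size 1 with flux magnitudes capped at 2. For a zero-length route
#' (source = target) the empty design is feasible and the thermodynamic row
#' is dropped (there is no net conversion to drive).
#'
#' @param net a `planted_network`.
#' @param ... overrides forwarded to [design_problem()].
#' @return A `design_problem`.
#' @export
planted_design <- function(net, ...) {
  .planted_problem(net$source, net$target, net$route_len, ...)
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted network: %s -> %s in %d steps, %d known reactions (seed %d)>\n",
              x$source, x$target, x$route_len, nrow(x$db$reactions), x$seed))
  invisible(x)
}
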