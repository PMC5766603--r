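## End-to-end orchestration: rule extraction runs, design runs, manifests,
## and the plumbing behind the command-line front ends in inst/cli/.

.read_config <- function(config) {
  if (is.list(config)) return(config)
  if (grepl("\\.ya?ml$", config) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

.write_manifest <- function(out_dir, inputs, extra = list()) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  hashes <- vapply(unlist(inputs), function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, character(1))
  manifest <- c(list(
    package = "moietypath",
    version = as.character(utils::packageVersion("moietypath")),
    r_version = R.version.string,
    inputs = as.list(stats::setNames(hashes, unlist(inputs)))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run rule extraction end to end
#'
#' Loads reactions and structures, extracts the unique rule set at every
#' requested moiety size, writes one rule file per size plus an extraction
#' report, and returns the report. Reactions that fail (missing structures,
#' elemental imbalance) are listed and skipped; the run continues.
#'
#' @param config list or path to a YAML/JSON file with fields `reactions`
#'   (TSV path), `structures` (SMILES table or SDF path), `lambdas` (integer
#'   vector, default 1:3), `out_dir`.
#' @return A tibble report (`lambda`, `n_rules`, `n_reactions`,
#'   `n_rejected`), invisibly; attribute `status` is 0 on success, 4 on input
#'   error, 3 if every reaction was rejected.
#' @export
run_extract <- function(config) {
  cfg <- .read_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    db <- load_reactions(cfg$reactions)
    mols <- read_structures(cfg$structures)
    lambdas <- as.integer(cfg$lambdas %||% 1:3)
    reg <- prime_registry()
    report <- purrr::map(lambdas, function(lam) {
      rs <- extract_rules(db, mols, lam, reg)
      write_rule_set(rs, file.path(out_dir, sprintf("rules_lambda%d.json", lam)))
      if (nrow(rs$rejected) > 0L) {
        readr::write_tsv(rs$rejected,
                         file.path(out_dir, sprintf("rejected_lambda%d.tsv", lam)))
      }
      glance(rs)
    }) |> bind_rows()
    readr::write_tsv(report, file.path(out_dir, "extraction_report.tsv"))
    .write_manifest(out_dir,
                    list(reactions = cfg$reactions, structures = cfg$structures),
                    list(lambdas = lambdas))
    status <- if (all(report$n_rules == 0L) && all(report$n_rejected > 0L)) 3L else 0L
    attr(report, "status") <- status
    report
  }, error = function(e) {
    rep <- tibble(lambda = integer(0), n_rules = integer(0),
                  n_reactions = integer(0), n_rejected = integer(0))
    attr(rep, "status") <- 4L
    attr(rep, "error") <- conditionMessage(e)
    rep
  })
  invisible(res)
}

# plain-text route table in the step-numbered style of design reports
.route_table <- function(ps, model) {
  lines <- character(0)
  for (i in seq_len(nrow(ps))) {
    s <- ps$solution[[i]]
    lines <- c(lines, sprintf("solution %d (objective %g, deltaG %s kcal):",
                              i, ps$objective[i],
                              ifelse(is.na(s$deltaG), "NA", format(s$deltaG))))
    act <- s$fluxes[s$fluxes$flux != 0L, ]
    for (k in seq_len(nrow(act))) {
      lines <- c(lines, sprintf("  step %d: %s (%s, flux %+d)", k, act$step[k],
                                act$type[k], act$flux[k]))
    }
    conv <- tryCatch(format_conversion(net_conversion(s, model)),
                     error = function(e) "no net conversion")
    lines <- c(lines, paste0("  net: ", conv), "")
  }
  lines
}

#' Run pathway design end to end
#'
#' Loads (or extracts) rules, builds the design MILP, enumerates solutions,
#' validates each, and writes JSON solution files plus a human-readable route
#' table and a manifest.
#'
#' @param config list or path to YAML/JSON with fields: `reactions`,
#'   `structures`, `thermo` (paths), optional `rules` (cached rule-set JSON),
#'   `lambda`, `source`, `target`, `exchange` (list metabolite -> c(lb, ub)),
#'   and optionally `objective`, `max_steps`, `max_rules`,
#'   `banned_exchanges`, `use_thermo`, `epsilon`, `flux_bound`,
#'   `max_solutions`, `organisms`, `pathways`, `out_dir`, `time_limit`.
#' @return The `pathway_set`, invisibly; attribute `status` is 0 when
#'   solutions were found, 3 when the design is infeasible, 4 on input error.
#' @export
run_design <- function(config) {
  cfg <- .read_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    db <- load_reactions(cfg$reactions)
    mols <- read_structures(cfg$structures)
    thermo <- if (!is.null(cfg$thermo)) load_thermo(cfg$thermo) else NULL
    lam <- as.integer(cfg$lambda %||% 2)
    reg <- prime_registry()
    rules <- if (!is.null(cfg$rules)) {
      read_rule_set(cfg$rules, reg)
    } else {
      extract_rules(db, mols, lam, reg)
    }
    sigs <- signature_index(mols, lam, reg)
    exg <- purrr::imap(cfg$exchange, function(b, m) {
      tibble(metabolite = m, lb = b[[1]], ub = b[[2]])
    }) |> bind_rows()
    prob <- design_problem(
      source = cfg$source, target = cfg$target, exchange = exg, lambda = lam,
      objective = cfg$objective %||% "min_total_steps",
      max_steps = cfg$max_steps, max_rules = cfg$max_rules,
      banned_exchanges = cfg$banned_exchanges %||% character(0),
      prices = unlist(cfg$prices),
      use_thermo = cfg$use_thermo %||% !is.null(thermo),
      epsilon = cfg$epsilon %||% 0.5,
      flux_bound = cfg$flux_bound %||% 10L,
      organisms = cfg$organisms, pathways = cfg$pathways
    )
    model <- build_design_model(prob, db, rules, sigs, thermo)
    ps <- solve_pathways(model, k = cfg$max_solutions %||% 10,
                         time_limit = cfg$time_limit %||% 300)
    for (i in seq_len(nrow(ps))) {
      s <- ps$solution[[i]]
      jsonlite::write_json(
        list(steps = s$fluxes[s$fluxes$flux != 0L, ],
             vimb = as.list(s$vimb[s$vimb != 0L]),
             vex = as.list(s$vex[s$vex != 0L]),
             objective = ps$objective[i], deltaG = s$deltaG,
             step_count = s$step_count, rule_count = s$rule_count,
             valid = ps$valid[i],
             validation = ps$validation[[i]]),
        file.path(out_dir, sprintf("solution_%02d.json", i)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    writeLines(.route_table(ps, model), file.path(out_dir, "routes.txt"))
    .write_manifest(out_dir,
                    list(reactions = cfg$reactions, structures = cfg$structures,
                         thermo = cfg$thermo, rules = cfg$rules),
                    list(lambda = lam, objective = prob$objective,
                         solver = "scipy-highs",
                         status = attr(ps, "status")))
    attr(ps, "exit_status") <- if (nrow(ps) > 0L) 0L else 3L
    ps
  }, error = function(e) {
    ps <- tibble()
    attr(ps, "exit_status") <- 4L
    attr(ps, "error") <- conditionMessage(e)
    ps
  })
  invisible(res)
}

#' Write the bundled fixture files to a directory
#'
#' Materializes the two-decarboxylase toy system (reactions, structures,
#' thermodynamics) and optionally a seeded planted network as plain-text
#' files, so the command-line tools can be exercised without any external
#' database.
#'
#' @param out_dir output directory.
#' @param seed seed for the planted network; `NULL` writes the toy system
#'   only.
#' @return Paths of the written files, invisibly.
#' @export
write_fixture_files <- function(out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy <- toy_decarboxylase_db()
  paths <- c(
    reactions = file.path(out_dir, "toy_reactions.tsv"),
    structures = file.path(out_dir, "toy_structures.tsv"),
    thermo = file.path(out_dir, "toy_thermo.tsv")
  )
  write_reactions(toy$db, paths[["reactions"]])
  readr::write_tsv(
    tibble(id = names(toy$mols),
           smiles = purrr::map_chr(toy$mols, ~ .x$source)),
    paths[["structures"]])
  readr::write_tsv(
    tibble(metabolite = names(toy$thermo), dgf = as.numeric(toy$thermo)),
    paths[["thermo"]])
  if (!is.null(seed)) {
    net <- planted_network(seed = seed)
    p2 <- c(planted_reactions = file.path(out_dir, "planted_reactions.tsv"),
            planted_structures = file.path(out_dir, "planted_structures.tsv"),
            planted_thermo = file.path(out_dir, "planted_thermo.tsv"))
    write_reactions(net$db, p2[["planted_reactions"]])
    readr::write_tsv(
      tibble(id = names(net$mols),
             smiles = purrr::map_chr(net$mols, ~ .x$source)),
      p2[["planted_structures"]])
    readr::write_tsv(
      tibble(metabolite = names(net$thermo), dgf = as.numeric(net$thermo)),
      p2[["planted_thermo"]])
    paths <- c(paths, p2)
  }
  invisible(paths)
}
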