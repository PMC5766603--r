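#' @importFrom rlang .data
NULL

## ---- design problem -------------------------------------------------------

#' Specify a pathway-design problem
#'
#' The design selects integer fluxes through known reactions (`v_j`), through
#' reaction rules (`v_r`), the per-metabolite imbalance fluxes linking the two
#' networks (`v_imb`), and net exchange fluxes (`v_EX`, positive = export),
#' subject to component balance, moiety balance, optional thermodynamic
#' feasibility and design criteria.
#'
#' @param source,target metabolite ids; both must appear in `exchange`.
#' @param exchange tibble with columns `metabolite`, `lb`, `ub`: the allowed
#'   exchange metabolites and bounds on their exchange flux (mol per mol of
#'   designed conversion). All other metabolites are fixed to zero exchange.
#' @param lambda moiety size the design works at; must match the rule set and
#'   signatures (sizes are never mixed within one design).
#' @param objective one of `"min_total_steps"`, `"min_rules"`, `"max_profit"`.
#' @param max_steps,max_rules optional caps on the number of steps (known +
#'   rule) and on the number of rule steps.
#' @param banned_exchanges metabolites whose exchange is forced to zero even
#'   if listed in `exchange`.
#' @param prices named vector of per-mol prices used by `"max_profit"`.
#' @param use_thermo if `TRUE`, require the overall standard Gibbs energy of
#'   the net conversion to be at most `-epsilon` kcal. Disable for databases
#'   without thermodynamic coverage, or to surface thermodynamically
#'   infeasible candidates for inspection.
#' @param epsilon thermodynamic strictness margin in kcal (> 0).
#' @param flux_bound big-M bound on every flux magnitude.
#' @param directions named character vector pinning step directions
#'   (`"forward"` or `"reverse"`); steps default to reversible.
#' @param organisms,pathways optional character vectors of allowed
#'   organism/pathway annotation labels; when given, a known reaction (or a
#'   rule, through its member reactions) may only carry flux if it carries at
#'   least one allowed label.
#' @param cofactor_groups optional named list of metabolite-id vectors
#'   (cofactor pairs); at most `max_cofactor_groups` groups may be touched by
#'   active steps.
#' @param max_cofactor_groups cap used with `cofactor_groups` (default 1).
#' @return A `design_problem`.
#' @export
design_problem <- function(source, target, exchange, lambda = 2,
                           objective = c("min_total_steps", "min_rules", "max_profit"),
                           max_steps = NULL, max_rules = NULL,
                           banned_exchanges = character(0),
                           prices = NULL, use_thermo = TRUE, epsilon = 0.5,
                           flux_bound = 10L, directions = NULL,
                           organisms = NULL, pathways = NULL,
                           cofactor_groups = NULL, max_cofactor_groups = 1L) {
  objective <- match.arg(objective)
  exchange <- as_tibble(exchange)
  if (!all(c("metabolite", "lb", "ub") %in% names(exchange))) {
    abort("`exchange` needs columns metabolite, lb, ub")
  }
  if (!all(c(source, target) %in% exchange$metabolite)) {
    abort("source and target must be listed in `exchange`")
  }
  if (any(exchange$lb > exchange$ub)) abort("exchange bounds need lb <= ub")
  if (any(!is.finite(exchange$lb) | !is.finite(exchange$ub))) {
    abort("exchange bounds must be finite")
  }
  if (epsilon <= 0) abort("`epsilon` must be positive")
  structure(
    list(source = source, target = target, exchange = exchange,
         lambda = as.integer(lambda), objective = objective,
         max_steps = max_steps, max_rules = max_rules,
         banned_exchanges = banned_exchanges, prices = prices,
         use_thermo = use_thermo, epsilon = epsilon,
         flux_bound = as.integer(flux_bound),
         directions = directions, organisms = organisms, pathways = pathways,
         cofactor_groups = cofactor_groups,
         max_cofactor_groups = as.integer(max_cofactor_groups)),
    class = "design_problem"
  )
}

#' @export
print.design_problem <- function(x, ...) {
  cat(sprintf("<design problem: %s -> %s, lambda=%d, objective=%s>\n",
              x$source, x$target, x$lambda, x$objective))
  invisible(x)
}

## ---- model build ----------------------------------------------------------

.INF <- 1e30

# rule change matrix (moieties x rules) and signature matrix helpers
.rule_matrix <- function(rules, moieties) {
  ids <- rules$info$rule_id
  T_ <- matrix(0L, nrow = length(moieties), ncol = length(ids),
               dimnames = list(as.character(moieties), ids))
  if (nrow(rules$rules) > 0L) {
    T_[cbind(match(rules$rules$moiety, moieties),
             match(rules$rules$rule_id, ids))] <- rules$rules$change
  }
  T_
}

.sig_matrix <- function(sigs, moieties, mets) {
  C_ <- matrix(0L, nrow = length(moieties), ncol = length(mets),
               dimnames = list(as.character(moieties), mets))
  s <- sigs[sigs$metabolite %in% mets, ]
  C_[cbind(match(s$moiety, moieties), match(s$metabolite, mets))] <- s$count
  C_
}

# annotation admissibility under an allowed-label filter (NULL = no filter)
.allowed <- function(labels, allowed) {
  if (is.null(allowed)) return(TRUE)
  length(intersect(labels, allowed)) > 0L
}

#' Build the pathway-design MILP
#'
#' Assembles component-balance rows (one per metabolite), moiety-balance rows
#' (one per moiety observed in the signatures or rules at the problem's
#' moiety size), exchange bounds, the thermodynamic row, binary step
#' indicators linked to fluxes by big-M rows in both directions, step and
#' rule caps, annotation and cofactor restrictions, and the configured
#' objective. Fluxes are integers; reversible steps are split into
#' nonnegative forward/reverse parts with one indicator per direction.
#'
#' @param problem a `design_problem`.
#' @param db a `reaction_db` of known reactions.
#' @param rules a `rule_set` at `problem$lambda`, or `NULL` for a design over
#'   known reactions only.
#' @param sigs a `signature_index` covering every database and exchange
#'   metabolite at `problem$lambda`.
#' @param thermo a `thermo_table`; required when `problem$use_thermo` or the
#'   objective needs it, must cover all exchange metabolites.
#' @return A `design_model`.
#' @export
build_design_model <- function(problem, db, rules, sigs, thermo = NULL) {
  stopifnot(inherits(problem, "design_problem"), inherits(db, "reaction_db"))
  lam <- problem$lambda
  if (!is.null(rules) && rules$lambda != lam) {
    abort(sprintf("rule set is at lambda=%d but the problem asks lambda=%d; sizes are never mixed",
                  rules$lambda, lam))
  }
  if (!is.null(attr(sigs, "lambda")) && attr(sigs, "lambda") != lam) {
    abort(sprintf("signatures are at lambda=%d but the problem asks lambda=%d",
                  attr(sigs, "lambda"), lam))
  }
  ex <- problem$exchange
  ex$lb[ex$metabolite %in% problem$banned_exchanges] <- 0
  ex$ub[ex$metabolite %in% problem$banned_exchanges] <- 0
  mets <- sort(union(db_metabolites(db), ex$metabolite))
  nosig <- setdiff(mets, unique(sigs$metabolite))
  if (length(nosig) > 0L) {
    abort(paste0("no signature for metabolite(s): ", paste(nosig, collapse = ", ")))
  }
  if (problem$use_thermo) {
    if (is.null(thermo)) abort("thermodynamic constraint requested but no thermo table given")
    missing <- setdiff(ex$metabolite, names(thermo))
    if (length(missing) > 0L) {
      abort(paste0("no formation energy for exchange metabolite(s): ",
                   paste(missing, collapse = ", ")))
    }
  }

  rxns <- db$reactions$reaction
  rule_ids <- if (is.null(rules)) character(0) else rules$info$rule_id
  steps <- tibble(
    step = c(rxns, rule_ids),
    type = c(rep("known", length(rxns)), rep("rule", length(rule_ids)))
  )
  ns <- nrow(steps)
  M <- problem$flux_bound

  # reversibility / pins / annotation admissibility per step
  rev_known <- db$reactions$reversible
  rev_rule <- if (is.null(rules)) logical(0) else rules$info$reversible
  reversible <- c(rev_known, rev_rule)
  dirpin <- rep(NA_character_, ns)
  if (!is.null(problem$directions)) {
    hit <- match(steps$step, names(problem$directions))
    dirpin[!is.na(hit)] <- unname(problem$directions[hit[!is.na(hit)]])
  }
  ann_ok <- logical(ns)
  for (s in seq_len(ns)) {
    if (steps$type[s] == "known") {
      row <- db$reactions[db$reactions$reaction == steps$step[s], ]
      ok_org <- .allowed(row$organisms[[1]], problem$organisms)
      ok_pat <- .allowed(row$pathways[[1]], problem$pathways)
    } else {
      row <- rules$info[rules$info$rule_id == steps$step[s], ]
      ok_org <- .allowed(row$organisms[[1]], problem$organisms)
      ok_pat <- .allowed(row$pathways[[1]], problem$pathways)
    }
    ann_ok[s] <- ok_org && ok_pat
  }

  # cofactor groups touched by each known reaction (rules: via members)
  cof <- problem$cofactor_groups
  ngrp <- length(cof %||% list())
  step_groups <- vector("list", ns)
  if (ngrp > 0L) {
    rx_groups <- lapply(rxns, function(j) {
      touched <- names(cof)[vapply(cof, function(g) {
        any(g %in% names(.stoich_vector(db, j)))
      }, logical(1))]
      touched
    })
    names(rx_groups) <- rxns
    for (s in seq_len(ns)) {
      step_groups[[s]] <- if (steps$type[s] == "known") {
        rx_groups[[steps$step[s]]]
      } else {
        members <- rules$info$member_reactions[[match(steps$step[s], rules$info$rule_id)]]
        unique(unlist(rx_groups[intersect(members, rxns)]))
      }
    }
  }

  ## variable layout: per step vp, vn, yp, yn; then vimb per metabolite;
  ## vex per exchange row; then cofactor binaries
  vars <- list()
  for (s in seq_len(ns)) {
    fwd_ok <- ann_ok[s] && !identical(dirpin[s], "reverse")
    rev_ok <- ann_ok[s] && reversible[s] && !identical(dirpin[s], "forward")
    vars[[length(vars) + 1L]] <- tibble(
      name = paste0(c("vp|", "vn|", "yp|", "yn|"), steps$step[s]),
      kind = c("vp", "vn", "yp", "yn"), step = steps$step[s], type = steps$type[s],
      lb = 0, ub = c(if (fwd_ok) M else 0, if (rev_ok) M else 0,
                     if (fwd_ok) 1 else 0, if (rev_ok) 1 else 0))
  }
  vars[[length(vars) + 1L]] <- tibble(
    name = paste0("vimb|", mets), kind = "vimb", step = mets, type = "met",
    lb = -.INF, ub = .INF)
  vars[[length(vars) + 1L]] <- tibble(
    name = paste0("vex|", ex$metabolite), kind = "vex", step = ex$metabolite,
    type = "met", lb = ex$lb, ub = ex$ub)
  if (ngrp > 0L) {
    vars[[length(vars) + 1L]] <- tibble(
      name = paste0("z|", names(cof)), kind = "z", step = names(cof),
      type = "cofactor", lb = 0, ub = 1)
  }
  vars <- bind_rows(vars)
  nv <- nrow(vars)
  col_of <- stats::setNames(seq_len(nv), vars$name)
  vp <- col_of[paste0("vp|", steps$step)]; vn <- col_of[paste0("vn|", steps$step)]
  yp <- col_of[paste0("yp|", steps$step)]; yn <- col_of[paste0("yn|", steps$step)]
  vimb <- col_of[paste0("vimb|", mets)]
  vex <- col_of[paste0("vex|", ex$metabolite)]

  S0 <- .stoich_matrix(db)
  # rows over the full metabolite set; exchange-only metabolites get zeros
  S <- matrix(0, nrow = length(mets), ncol = ncol(S0),
              dimnames = list(mets, colnames(S0)))
  S[rownames(S0), ] <- S0
  moieties <- sort(unique(c(
    sigs$moiety[sigs$metabolite %in% mets],
    if (!is.null(rules)) rules$rules$moiety else integer(0))))
  C_all <- .sig_matrix(sigs, moieties, mets)
  C_ex <- .sig_matrix(sigs, moieties, ex$metabolite)
  T_ <- if (is.null(rules)) {
    matrix(0L, nrow = length(moieties), ncol = 0L)
  } else .rule_matrix(rules, moieties)

  ri <- integer(0); ci <- integer(0); vv <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0); rlabel <- character(0)
  nrow_ <- 0L
  add_row <- function(cols, vals, lb, ub, label) {
    nrow_ <<- nrow_ + 1L
    keep <- vals != 0
    ri <<- c(ri, rep(nrow_, sum(keep))); ci <<- c(ci, cols[keep])
    vv <<- c(vv, vals[keep])
    rlb <<- c(rlb, lb); rub <<- c(rub, ub); rlabel <<- c(rlabel, label)
  }

  # (a) component balance: vimb_i - sum_j S_ij (vp_j - vn_j) = 0
  known <- steps$type == "known"
  for (i in seq_along(mets)) {
    srow <- S[mets[i], , drop = TRUE]
    cols <- c(vimb[i], vp[known], vn[known])
    vals <- c(1, -srow, srow)
    add_row(cols, vals, 0, 0, paste0("component|", mets[i]))
  }
  # (b) moiety balance:
  #   sum_ex C vex - sum_r T (vp_r - vn_r) - sum_i C vimb = 0
  isrule <- steps$type == "rule"
  for (m in seq_along(moieties)) {
    cols <- c(vex, vp[isrule], vn[isrule], vimb)
    vals <- c(C_ex[m, ], -T_[m, ], T_[m, ], -C_all[m, ])
    add_row(cols, vals, 0, 0, paste0("moiety|", moieties[m]))
  }
  # (e) indicator linking in both directions: y on <=> flux nonzero
  for (s in seq_len(ns)) {
    add_row(c(vp[s], yp[s]), c(1, -M), -.INF, 0, paste0("bigM+|", steps$step[s]))
    add_row(c(vp[s], yp[s]), c(1, -1), 0, .INF, paste0("lower+|", steps$step[s]))
    add_row(c(vn[s], yn[s]), c(1, -M), -.INF, 0, paste0("bigM-|", steps$step[s]))
    add_row(c(vn[s], yn[s]), c(1, -1), 0, .INF, paste0("lower-|", steps$step[s]))
    add_row(c(yp[s], yn[s]), c(1, 1), 0, 1, paste0("onedir|", steps$step[s]))
  }
  # (f) caps
  if (!is.null(problem$max_rules)) {
    add_row(c(yp[isrule], yn[isrule]), rep(1, 2 * sum(isrule)),
            0, problem$max_rules, "cap|rules")
  }
  if (!is.null(problem$max_steps)) {
    add_row(c(yp, yn), rep(1, 2 * ns), 0, problem$max_steps, "cap|steps")
  }
  # (d) thermodynamic feasibility on exchange fluxes
  if (problem$use_thermo) {
    dgf <- unclass(thermo)[ex$metabolite]
    add_row(vex, dgf, -.INF, -problem$epsilon, "thermo")
  }
  # cofactor-group selection
  if (ngrp > 0L) {
    zc <- stats::setNames(unname(col_of[paste0("z|", names(cof))]), names(cof))
    for (s in seq_len(ns)) {
      for (g in step_groups[[s]]) {
        add_row(c(yp[s], yn[s], zc[g]), c(1, 1, -1), -.INF, 0,
                paste0("cofactor|", steps$step[s], "|", g))
      }
    }
    add_row(zc, rep(1, ngrp), 0, problem$max_cofactor_groups, "cap|cofactor_groups")
  }

  obj <- numeric(nv)
  if (problem$objective == "min_total_steps") {
    obj[c(yp, yn)] <- 1
  } else if (problem$objective == "min_rules") {
    obj[c(yp[isrule], yn[isrule])] <- 1
  } else {
    if (is.null(problem$prices)) abort("max_profit objective needs `prices`")
    pr <- problem$prices[ex$metabolite]
    pr[is.na(pr)] <- 0
    obj[vex] <- -unname(pr)  # maximize profit == minimize negative profit
  }

  structure(
    list(vars = vars, steps = steps,
         con = list(row = ri, col = ci, val = vv, nrow = nrow_,
                    lb = rlb, ub = rub, label = rlabel),
         objective = obj, problem = problem, db = db, rules = rules,
         sigs = sigs, thermo = thermo, mets = mets, moieties = moieties,
         matrices = list(S = S, C_all = C_all, C_ex = C_ex, T = T_),
         cols = list(vp = vp, vn = vn, yp = yp, yn = yn, vimb = vimb, vex = vex)),
    class = "design_model"
  )
}

#' @export
print.design_model <- function(x, ...) {
  cat(sprintf("<design model: %d vars, %d rows (%d component, %d moiety), %d steps>\n",
              nrow(x$vars), x$con$nrow,
              sum(startsWith(x$con$label, "component|")),
              sum(startsWith(x$con$label, "moiety|")), nrow(x$steps)))
  invisible(x)
}

## ---- solver backend -------------------------------------------------------

.find_python <- function() {
  py <- getOption("moietypath.python", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    abort(paste("pathway design requires an MILP solver with integer variables;",
                "no `python` interpreter with scipy was found on the PATH"))
  }
  py
}

.backend_script <- function() {
  p <- system.file("python", "milp_backend.py", package = "moietypath")
  if (!nzchar(p)) abort("milp_backend.py not found in the installed package")
  p
}

.run_milp <- function(model, k, time_limit = 300) {
  indicators <- unname(c(model$cols$yp, model$cols$yn))
  payload <- list(
    nvar = nrow(model$vars),
    objective = model$objective,
    lb = model$vars$lb, ub = model$vars$ub,
    con = model$con[c("row", "col", "val", "nrow", "lb", "ub")],
    indicators = indicators,
    max_solutions = k,
    time_limit = time_limit
  )
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(.find_python(), c(.backend_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    abort(paste("MILP backend failed:", paste(status, collapse = "\n")))
  }
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

## ---- solutions ------------------------------------------------------------

.solution_from_x <- function(x, model) {
  vars <- model$vars; cols <- model$cols
  flux <- as.integer(round(x[cols$vp] - x[cols$vn]))
  fluxes <- tibble(step = model$steps$step, type = model$steps$type,
                   flux = flux) |>
    mutate(direction = dplyr::case_when(flux > 0 ~ "+", flux < 0 ~ "-",
                                        TRUE ~ NA_character_))
  vimb <- stats::setNames(as.integer(round(x[cols$vimb])), model$mets)
  vex <- stats::setNames(as.integer(round(x[cols$vex])),
                         model$problem$exchange$metabolite)
  active <- fluxes |> filter(.data$flux != 0)
  key <- paste0(sort(paste0(active$step, active$direction)), collapse = " ")
  dG <- if (!is.null(model$thermo) &&
            all(names(vex[vex != 0]) %in% names(model$thermo))) {
    overall_deltaG(vex, model$thermo)
  } else NA_real_
  structure(
    list(fluxes = fluxes, vimb = vimb, vex = vex,
         step_count = nrow(active), rule_count = sum(active$type == "rule"),
         deltaG = dG, key = key),
    class = "pathway_solution"
  )
}

#' @export
print.pathway_solution <- function(x, ...) {
  cat(sprintf("<pathway solution: %d steps (%d rules), deltaG=%s kcal>\n  %s\n",
              x$step_count, x$rule_count,
              ifelse(is.na(x$deltaG), "NA", format(x$deltaG)), x$key))
  invisible(x)
}

#' Solve a design model and enumerate alternative pathways
#'
#' Solves the MILP, then repeatedly adds an integer cut excluding the exact
#' active indicator pattern of each incumbent — the same step set used in a
#' different direction pattern counts as a distinct solution — and re-solves,
#' so up to `k` solutions are returned in non-worsening objective order.
#' Every returned solution is re-validated with integer arithmetic,
#' independently of the solver. Ties at equal objective are ordered
#' lexicographically by their sorted active-step lists, for reproducibility.
#'
#' @param model a `design_model`.
#' @param k maximum number of solutions.
#' @param time_limit solver time limit in seconds (whole enumeration).
#' @return A `pathway_set`: tibble with one row per solution (`objective`,
#'   `steps`, `step_count`, `rule_count`, `deltaG`, `valid`) and the full
#'   `pathway_solution` in the `solution` list-column. Attribute `status` is
#'   `"ok"`, `"infeasible"`, or `"partial"` (solver limit hit).
#' @export
solve_pathways <- function(model, k = 10, time_limit = 300) {
  stopifnot(inherits(model, "design_model"))
  res <- .run_milp(model, k, time_limit)
  sols <- list()
  if (length(res$solutions) > 0L && !is.null(res$solutions$x)) {
    xs <- res$solutions$x
    if (is.list(xs)) xs <- do.call(rbind, xs)
    if (is.null(dim(xs))) xs <- matrix(xs, nrow = 1)
    sols <- lapply(seq_len(nrow(xs)), function(i) .solution_from_x(xs[i, ], model))
  }
  out <- purrr::map2(sols, seq_along(sols), function(s, i) {
    rep <- validate_solution(s, model)
    tibble(objective = res$solutions$objective[i],
           steps = s$key, step_count = s$step_count, rule_count = s$rule_count,
           deltaG = s$deltaG, valid = all(rep$ok),
           solution = list(s), validation = list(rep))
  }) |> bind_rows()
  if (nrow(out) > 0L) {
    out <- out |> arrange(.data$objective, .data$steps)
  } else {
    out <- tibble(objective = numeric(0), steps = character(0),
                  step_count = integer(0), rule_count = integer(0),
                  deltaG = numeric(0), valid = logical(0),
                  solution = list(), validation = list())
  }
  attr(out, "status") <- res$status
  attr(out, "model") <- model
  class(out) <- c("pathway_set", class(out))
  out
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway set: %d solutions (status: %s)>\n",
              nrow(x), attr(x, "status")))
  if (nrow(x) > 0L) print(as_tibble(x)[, c("objective", "steps", "deltaG", "valid")])
  invisible(x)
}

#' Re-validate a pathway solution with integer arithmetic
#'
#' Recomputes, independently of the solver: every component-balance row,
#' every moiety-balance row, the thermodynamic requirement, the step and rule
#' caps, and the elemental balance of the net conversion. An all-zero
#' solution with zero exchange is valid but flagged `"empty design"`.
#'
#' @param sol a `pathway_solution`.
#' @param model the `design_model` it came from.
#' @return A tibble `check`, `item`, `residual`, `ok`; attribute `flags`.
#' @export
validate_solution <- function(sol, model) {
  mm <- model$matrices
  p <- model$problem
  vj <- sol$fluxes$flux[sol$fluxes$type == "known"]
  vr <- sol$fluxes$flux[sol$fluxes$type == "rule"]
  comp <- as.integer(sol$vimb - as.vector(mm$S %*% vj))
  rows <- list(tibble(check = "component", item = model$mets,
                      residual = comp, ok = comp == 0L))
  moi <- as.integer(as.vector(mm$C_ex %*% sol$vex) -
                      (if (length(vr)) as.vector(mm$T %*% vr) else 0L) -
                      as.vector(mm$C_all %*% sol$vimb))
  rows[[2]] <- tibble(check = "moiety", item = as.character(model$moieties),
                      residual = moi, ok = moi == 0L)
  if (p$use_thermo) {
    dg <- overall_deltaG(sol$vex, model$thermo)
    rows[[3]] <- tibble(check = "thermo", item = "overall_deltaG",
                        residual = dg, ok = dg <= -p$epsilon + 1e-9)
  }
  if (!is.null(p$max_steps)) {
    rows[[length(rows) + 1L]] <- tibble(check = "cap", item = "max_steps",
                                        residual = sol$step_count,
                                        ok = sol$step_count <= p$max_steps)
  }
  if (!is.null(p$max_rules)) {
    rows[[length(rows) + 1L]] <- tibble(check = "cap", item = "max_rules",
                                        residual = sol$rule_count,
                                        ok = sol$rule_count <= p$max_rules)
  }
  # element audit of the net conversion, via moiety center elements
  centers <- .registry_centers(attr(model$sigs, "registry") %||% default_registry())
  elem <- tibble(metabolite = rep(colnames(mm$C_ex), each = nrow(mm$C_ex)),
                 moiety = rep(rownames(mm$C_ex), times = ncol(mm$C_ex)),
                 count = as.vector(mm$C_ex)) |>
    filter(.data$count > 0) |>
    mutate(element = unname(centers[.data$moiety]),
           vex = sol$vex[.data$metabolite]) |>
    group_by(.data$element) |>
    summarise(residual = sum(.data$count * .data$vex), .groups = "drop")
  rows[[length(rows) + 1L]] <- tibble(check = "element", item = elem$element,
                                      residual = as.numeric(elem$residual),
                                      ok = elem$residual == 0)
  out <- bind_rows(rows)
  flags <- character(0)
  if (sol$step_count == 0L && all(sol$vex == 0L)) flags <- c(flags, "empty design")
  attr(out, "flags") <- flags
  out
}

#' Net conversion of a pathway solution
#'
#' Restricts the exchange fluxes to their nonzero entries and normalizes so
#' the target's coefficient is +1 when the target is exported.
#'
#' @param sol a `pathway_solution`.
#' @param model the `design_model` it came from.
#' @return A tibble `metabolite`, `coef` (negative = consumed).
#' @export
net_conversion <- function(sol, model) {
  tgt <- model$problem$target
  v <- sol$vex[sol$vex != 0L]
  if (!tgt %in% names(v) || v[[tgt]] == 0L) {
    abort("net conversion undefined: the target carries zero exchange flux")
  }
  scale <- v[[tgt]]
  tibble(metabolite = names(v), coef = unname(v / scale)) |>
    arrange(dplyr::desc(.data$coef))
}

# human-readable "A + 2 B -> C" form
format_conversion <- function(conv) {
  side <- function(d) paste(purrr::map2_chr(d$metabolite, abs(d$coef), function(m, c) {
    if (c == 1) m else paste(c, m)
  }), collapse = " + ")
  paste(side(conv[conv$coef < 0, ]), "->", side(conv[conv$coef > 0, ]))
}

#' @export
tidy.pathway_set <- function(x, ...) {
  purrr::imap(x$solution, function(s, i) {
    mutate(filter(s$fluxes, .data$flux != 0), solution = i, .before = 1)
  }) |> bind_rows()
}

#' @export
glance.pathway_set <- function(x, ...) {
  tibble(n_solutions = nrow(x), status = attr(x, "status"),
         best_objective = if (nrow(x)) min(x$objective) else NA_real_,
         all_valid = if (nrow(x)) all(x$valid) else NA)
}

#' Plot the step usage of an enumerated pathway set
#'
#' One tile per (solution, active step), colored by signed integer flux.
#'
#' @param object a `pathway_set`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$solution), y = .data$step,
                                  fill = .data$flux)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "solution", y = "step", fill = "flux") +
    ggplot2::theme_minimal()
}

## ---- brute-force oracle ---------------------------------------------------

#' Enumerate feasible designs by exhaustive integer search
#'
#' Independent cross-check for [solve_pathways()]: walks every integer flux
#' assignment within bounds (known reactions, rules, exchange fluxes), checks
#' component balance (imbalances are implied), moiety balance, thermodynamics
#' and caps with plain integer arithmetic, and returns the set of feasible
#' designs keyed by active step set and direction pattern. Intended for small
#' planted networks; refuses grids beyond `max_grid` candidate vectors.
#'
#' @param model a `design_model`.
#' @param max_grid largest number of candidate flux vectors to examine.
#' @return A tibble `key`, `step_count`, `rule_count` (unique designs; the
#'   empty design is included when feasible with key `""`).
#' @export
enumerate_designs_bruteforce <- function(model, max_grid = 3e7) {
  p <- model$problem
  mm <- model$matrices
  steps <- model$steps
  vars <- model$vars
  ns <- nrow(steps)
  # per-step signed bounds from the split-variable bounds
  ub_p <- vars$ub[match(paste0("vp|", steps$step), vars$name)]
  ub_n <- vars$ub[match(paste0("vn|", steps$step), vars$name)]
  ex <- p$exchange
  ex$lb[ex$metabolite %in% p$banned_exchanges] <- 0
  ex$ub[ex$metabolite %in% p$banned_exchanges] <- 0
  lo <- c(-ub_n, ex$lb); hi <- c(ub_p, ex$ub)
  sizes <- hi - lo + 1
  if (prod(sizes) > max_grid) {
    abort(sprintf("brute-force grid too large (%.3g candidate vectors)", prod(sizes)))
  }
  # equality system over x = (v_steps, vex):
  #   C_ex vex - T v_rules - C_all S v_known = 0  for every moiety
  isrule <- steps$type == "rule"
  # columns in the (known..., rules..., vex...) order used by `lo`
  A <- matrix(0, nrow = nrow(mm$C_all), ncol = ns + nrow(ex))
  A[, which(!isrule)] <- -(mm$C_all %*% mm$S)
  if (any(isrule)) A[, which(isrule)] <- -mm$T
  A[, ns + seq_len(nrow(ex))] <- mm$C_ex
  dgf <- if (p$use_thermo) unclass(model$thermo)[ex$metabolite] else NULL

  nvar <- length(lo)
  total <- prod(sizes)
  base <- c(1, cumprod(sizes))[seq_len(nvar)]
  chunk <- 200000L
  found <- new.env(parent = emptyenv())
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    X <- matrix(0L, nrow = length(idx), ncol = nvar)
    for (v in seq_len(nvar)) {
      X[, v] <- as.integer(lo[v] + (idx %/% base[v]) %% sizes[v])
    }
    ok <- rowSums(abs(X %*% t(A))) == 0
    if (p$use_thermo && any(ok)) {
      dG <- X[, ns + seq_len(nrow(ex)), drop = FALSE] %*% dgf
      ok <- ok & (dG <= -p$epsilon + 1e-9)
    }
    if (!any(ok)) next
    Xf <- X[ok, , drop = FALSE]
    sc <- rowSums(Xf[, seq_len(ns), drop = FALSE] != 0L)
    rc <- if (any(isrule)) {
      rowSums(Xf[, which(isrule), drop = FALSE] != 0L)
    } else rep(0L, nrow(Xf))
    keep <- rep(TRUE, nrow(Xf))
    if (!is.null(p$max_steps)) keep <- keep & sc <= p$max_steps
    if (!is.null(p$max_rules)) keep <- keep & rc <= p$max_rules
    Xf <- Xf[keep, , drop = FALSE]; sc <- sc[keep]; rc <- rc[keep]
    for (r in seq_len(nrow(Xf))) {
      v <- Xf[r, seq_len(ns)]
      act <- which(v != 0L)
      key <- paste0(sort(paste0(steps$step[act],
                                ifelse(v[act] > 0, "+", "-"))), collapse = " ")
      if (is.null(found[[paste0("k", key)]])) {
        found[[paste0("k", key)]] <- list(key = key, step_count = sc[r],
                                          rule_count = rc[r])
      }
    }
  }
  vals <- mget(ls(found), envir = found)
  if (length(vals) == 0L) {
    return(tibble(key = character(0), step_count = integer(0),
                  rule_count = integer(0)))
  }
  purrr::map(vals, ~ tibble(key = .x$key, step_count = .x$step_count,
                            rule_count = .x$rule_count)) |>
    bind_rows() |> arrange(.data$step_count, .data$key)
}
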