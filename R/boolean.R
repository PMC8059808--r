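# Generic vector-based Boolean network engine with synchronous updates,
# toggleable crosstalk rules, knockouts, and steady-state/limit-cycle
# detection.
#
# Components carry named binary fields ("Comp.field"): metabolites and
# target-gene groups a single `value`, proteins and enzymes at least
# `present` and a (de)phosphorylation/conformation `state`. Rules are
# if/then/else clauses evaluated on the previous state only; crosstalk
# clauses carry an id and can be switched off, in which case the base
# rule applies (gap-filling else semantics).

#' Parse and validate a Boolean ruleset
#'
#' Accepts a JSON file path or an equivalent nested list. See the packaged
#' yeast ruleset (`system.file("extdata", "yeast_signaling.json",
#' package = "boolec")`) for the schema: per component a `class`, named
#' `fields` with `default` and optionally a `rule`
#' (`clauses` + `if`/`then`/`else`), and an `activity` expression.
#'
#' @param x path to a JSON ruleset or a list in the same shape.
#' @return Object of class `boolean_ruleset`.
#' @export
parse_ruleset <- function(x) {
  j <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = FALSE) else x
  comps <- j$components
  ids <- vapply(comps, function(cp) cp$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate component id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  inputs <- unlist(j$inputs) %||% character()
  classes <- vapply(comps, function(cp) cp$class %||% "protein", character(1))
  names(classes) <- ids

  fields <- character(); defaults <- integer(); rules <- list()
  activities <- list(); crosstalk_ids <- character()
  for (cp in comps) {
    fl <- cp$fields
    if (is.null(fl)) stop(sprintf("component '%s' declares no fields", cp$id))
    for (fname in names(fl)) {
      key <- paste0(cp$id, ".", fname)
      if (key %in% fields) stop(sprintf("field '%s' declared twice", key))
      fields <- c(fields, key)
      defaults[key] <- as.integer(fl[[fname]]$default %||% 0L)
      rl <- fl[[fname]]$rule
      if (!is.null(rl)) {
        if (is.null(rl$`if`) || is.null(rl$then) || is.null(rl$`else`)) {
          stop(sprintf("rule for '%s' lacks an if/then/else branch", key))
        }
        clauses <- lapply(rl$clauses %||% list(), function(cl) {
          if (is.null(cl$crosstalk)) {
            stop(sprintf("clause for '%s' lacks a crosstalk id", key))
          }
          crosstalk_ids <<- union(crosstalk_ids, cl$crosstalk)
          list(crosstalk = cl$crosstalk,
               cond = parse(text = cl$`if`)[[1]],
               then = as.integer(cl$then))
        })
        rules[[key]] <- list(clauses = clauses,
                             cond = parse(text = rl$`if`)[[1]],
                             then = as.integer(rl$then),
                             els = as.integer(rl$`else`))
      }
    }
    act <- cp$activity
    if (is.null(act)) {
      if (classes[[cp$id]] %in% c("metabolite", "target_gene_group")) {
        act <- paste0(cp$id, ".value")
      } else {
        stop(sprintf("component '%s' (class %s) lacks an activity expression",
                     cp$id, classes[[cp$id]]))
      }
    }
    activities[[cp$id]] <- parse(text = act)[[1]]
  }
  rs <- structure(list(name = j$name %||% "ruleset", inputs = inputs,
                       components = ids, classes = classes, fields = fields,
                       defaults = defaults, rules = rules,
                       activities = activities,
                       crosstalks = crosstalk_ids),
                  class = "boolean_ruleset")
  .validate_ruleset(rs)
  rs
}

.validate_ruleset <- function(rs) {
  allowed <- c(rs$fields, paste0(rs$components, ".active"), rs$inputs)
  check_expr <- function(e, where) {
    unknown <- setdiff(all.vars(e), allowed)
    if (length(unknown)) {
      stop(sprintf("%s references undeclared name(s): %s", where,
                   paste(unknown, collapse = ", ")))
    }
  }
  for (key in names(rs$rules)) {
    r <- rs$rules[[key]]
    check_expr(r$cond, sprintf("rule for '%s'", key))
    for (cl in r$clauses) check_expr(cl$cond, sprintf("clause for '%s'", key))
  }
  for (cid in names(rs$activities)) {
    check_expr(rs$activities[[cid]], sprintf("activity of '%s'", cid))
  }
  invisible(rs)
}

#' Load the packaged yeast nutrient-signaling ruleset
#'
#' A curated Boolean model of the PKA, SNF1 and TORC1 pathways with their
#' crosstalks, responsive to glucose and nitrogen inputs.
#'
#' @return A `boolean_ruleset`.
#' @export
yeast_ruleset <- function() {
  parse_ruleset(system.file("extdata", "yeast_signaling.json",
                            package = "boolec"))
}

#' Default (all-defaults) Boolean state of a ruleset
#' @param rules a `boolean_ruleset`.
#' @return Named integer vector over all fields.
#' @export
initial_state <- function(rules) {
  st <- rs_state <- rules$defaults
  st
}

.presence_fields <- function(rules, knockouts) {
  out <- character()
  for (ko in knockouts) {
    f <- grep(paste0("^", ko, "\\.(present|value)$"), rules$fields,
              value = TRUE)
    if (!length(f)) stop(sprintf("unknown knockout component '%s'", ko))
    out <- c(out, f)
  }
  out
}

.state_env <- function(state, rules, inputs) {
  env <- new.env(parent = baseenv())
  for (key in names(state)) assign(key, state[[key]], envir = env)
  for (key in names(inputs)) assign(key, as.integer(inputs[[key]]), envir = env)
  # component activities of the *previous* state are visible to rules
  for (cid in rules$components) {
    assign(paste0(cid, ".active"),
           as.integer(as.logical(eval(rules$activities[[cid]], env))),
           envir = env)
  }
  env
}

#' One synchronous update step
#'
#' Every field is recomputed from the previous state only. Knocked-out
#' components have their presence forced to 0 both in the evaluation
#' environment and in the returned state; crosstalk clauses whose flag is
#' off are skipped so the base (else-gap-filled) rule applies.
#'
#' @param state named integer vector over the ruleset's fields.
#' @param rules a `boolean_ruleset`.
#' @param inputs named binary vector over the ruleset's inputs
#'   (e.g. `c(glucose = 1, nitrogen = 1)`).
#' @param crosstalk_flags named logical vector keyed by crosstalk id;
#'   missing ids default to on.
#' @param knockouts character vector of component ids.
#' @return The updated state.
#' @export
synchronous_step <- function(state, rules, inputs, crosstalk_flags = NULL,
                             knockouts = character()) {
  miss <- setdiff(rules$fields, names(state))
  if (length(miss)) stop(sprintf("state lacks field(s): %s",
                                 paste(miss, collapse = ", ")))
  ko_fields <- .presence_fields(rules, knockouts)
  state[ko_fields] <- 0L
  env <- .state_env(state, rules, inputs)
  flag_on <- function(id) {
    if (is.null(crosstalk_flags) || is.na(crosstalk_flags[id]) ||
        !id %in% names(crosstalk_flags)) TRUE
    else isTRUE(as.logical(crosstalk_flags[[id]]))
  }
  new_state <- state
  for (key in names(rules$rules)) {
    r <- rules$rules[[key]]
    val <- NULL
    for (cl in r$clauses) {
      if (flag_on(cl$crosstalk) && isTRUE(as.logical(eval(cl$cond, env)))) {
        val <- cl$then
        break
      }
    }
    if (is.null(val)) {
      val <- if (isTRUE(as.logical(eval(r$cond, env)))) r$then else r$els
    }
    new_state[[key]] <- as.integer(val)
  }
  new_state[ko_fields] <- 0L
  new_state
}

#' Iterate synchronous updates to a Boolean steady state
#'
#' Stops when no update changes the state vector (a fixed point). If a state
#' recurs without being a fixed point, the limit cycle is reported as a
#' first-class result rather than an error.
#'
#' @inheritParams synchronous_step
#' @param initial starting state; defaults to the ruleset's defaults, which
#'   chains naturally: pass a previous condition's steady state to simulate
#'   consecutive nutrient shifts.
#' @param max_iter maximum number of iterations before a non-convergence
#'   error.
#' @return List with `trajectory` (matrix, iterations x fields, row 0 = the
#'   initial state), `steady_state` (or `NULL`), `cycle` (`NULL` or a list
#'   with `period` and `states`), and `iterations`.
#' @export
run_to_steady_state <- function(rules, inputs, initial = NULL,
                                crosstalk_flags = NULL,
                                knockouts = character(), max_iter = 100) {
  stopifnot(max_iter >= 1)
  state <- initial %||% initial_state(rules)
  state <- state[rules$fields]
  traj <- list(state)
  seen <- stats::setNames(1L, paste(state, collapse = ""))
  for (it in seq_len(max_iter)) {
    nxt <- synchronous_step(state, rules, inputs, crosstalk_flags, knockouts)
    traj[[length(traj) + 1]] <- nxt
    if (identical(unname(nxt[rules$fields]), unname(state[rules$fields]))) {
      tm <- do.call(rbind, traj)
      rownames(tm) <- seq_len(nrow(tm)) - 1L
      return(list(trajectory = tm, steady_state = nxt, cycle = NULL,
                  iterations = it))
    }
    key <- paste(nxt, collapse = "")
    if (!is.na(seen[key])) {
      first <- seen[[key]]
      period <- length(traj) - first
      tm <- do.call(rbind, traj)
      rownames(tm) <- seq_len(nrow(tm)) - 1L
      return(list(trajectory = tm, steady_state = NULL,
                  cycle = list(period = period,
                               states = tm[first:(length(traj) - 1), ,
                                           drop = FALSE]),
                  iterations = it))
    }
    seen[key] <- length(traj)
    state <- nxt
  }
  stop(sprintf("no steady state or cycle within %d iterations", max_iter))
}

#' Project a state vector onto per-component activities
#'
#' Translates the state vector into a single binary activity value per
#' component via the component's declared activity expression (for instance
#' present AND correctly phosphorylated).
#'
#' @inheritParams synchronous_step
#' @return Named integer vector over component ids.
#' @export
project_activity <- function(state, rules, inputs = NULL,
                             knockouts = character()) {
  state[.presence_fields(rules, knockouts)] <- 0L
  env <- new.env(parent = baseenv())
  for (key in names(state)) assign(key, state[[key]], envir = env)
  if (!is.null(inputs)) {
    for (key in names(inputs)) {
      assign(key, as.integer(inputs[[key]]), envir = env)
    }
  }
  vapply(rules$components, function(cid) {
    as.integer(as.logical(eval(rules$activities[[cid]], env)))
  }, integer(1))
}

#' Chained steady states across nutrient conditions
#'
#' Runs the ruleset through a sequence of nutrient conditions, using each
#' reached steady state as the initial condition of the next (the first runs
#' from the ruleset defaults).
#'
#' @inheritParams synchronous_step
#' @param conditions data.frame with one row per condition and one column
#'   per ruleset input.
#' @return List of [run_to_steady_state()] results, one per condition.
#' @export
steady_state_chain <- function(rules, conditions, crosstalk_flags = NULL,
                               knockouts = character(), max_iter = 100) {
  state <- initial_state(rules)
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    inputs <- stats::setNames(as.integer(conditions[i, rules$inputs]),
                              rules$inputs)
    res <- run_to_steady_state(rules, inputs, initial = state,
                               crosstalk_flags = crosstalk_flags,
                               knockouts = knockouts, max_iter = max_iter)
    if (is.null(res$steady_state)) {
      stop(sprintf("condition %d reached a limit cycle, not a steady state", i))
    }
    state <- res$steady_state
    out[[i]] <- res
  }
  out
}

#' @export
print.boolean_ruleset <- function(x, ...) {
  census <- table(x$classes)
  cat(sprintf("boolean_ruleset '%s': %d components (%s), %d crosstalks\n",
              x$name, length(x$components),
              paste(sprintf("%s=%d", names(census), census), collapse = ", "),
              length(x$crosstalks)))
  invisible(x)
}
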