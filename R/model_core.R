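# Data model and I/O for stoichiometric metabolic models.
#
# A stoich_model is a plain list:
#   metabolites : data.frame(id, name, compartment)
#   reactions   : data.frame(id, lb, ub, reversible, gene_rule, subsystem)
#   stoich      : named list, reaction id -> named numeric (metabolite -> coef)
#   genes       : character vector
#   objective   : named numeric, reaction id -> integer coefficient
# Units are fixed globally: fluxes mmol/gDW/h, kcat 1/h, Mw g/mmol,
# protein pool g/gDW. Conversions happen only at file boundaries.

#' Construct a stoichiometric model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `reversible`,
#'   `gene_rule`, `subsystem`.
#' @param stoich named list mapping each reaction id to a named numeric vector
#'   of metabolite coefficients (negative = consumed).
#' @param genes character vector of gene ids.
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids (the vector of the FBA objective).
#' @return A validated object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, stoich, genes = character(),
                         objective = numeric()) {
  m <- structure(list(metabolites = as.data.frame(metabolites),
                      reactions = as.data.frame(reactions),
                      stoich = stoich, genes = genes,
                      objective = objective),
                 class = "stoich_model")
  validate_stoich_model(m)
  m
}

#' Validate a stoichiometric model's invariants
#'
#' Checks that every stoichiometry key is a declared metabolite, that
#' `lb <= ub` for every reaction, that the reversible flag corresponds to
#' `lb < 0`, and that gene rules reference only declared genes.
#'
#' @param model a `stoich_model`.
#' @return The model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_stoich_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn <- model$reactions
  if (anyDuplicated(met_ids)) stop("duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) stop("duplicated reaction ids")
  if (!setequal(names(model$stoich), rxn$id)) {
    stop("stoichiometry entries do not match declared reactions")
  }
  for (rid in rxn$id) {
    mets <- names(model$stoich[[rid]])
    unknown <- setdiff(mets, met_ids)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   rid, paste(unknown, collapse = ", ")))
    }
  }
  if (any(rxn$lb > rxn$ub)) {
    stop(sprintf("lb > ub for reaction(s): %s",
                 paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
  }
  if (any(rxn$reversible != (rxn$lb < 0))) {
    stop(sprintf("reversible flag inconsistent with lb for: %s",
                 paste(rxn$id[rxn$reversible != (rxn$lb < 0)], collapse = ", ")))
  }
  used_genes <- unique(unlist(lapply(rxn$gene_rule, function(g) {
    unlist(parse_gene_rule(g))
  })))
  unknown <- setdiff(used_genes, model$genes)
  if (length(unknown)) {
    stop(sprintf("gene rules reference undeclared gene(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  obj_unknown <- setdiff(names(model$objective), rxn$id)
  if (length(obj_unknown)) {
    stop(sprintf("objective references unknown reaction(s): %s",
                 paste(obj_unknown, collapse = ", ")))
  }
  invisible(model)
}

#' Parse a reaction equation string
#'
#' Understands the `"A + 2 B -> C"` dialect; `"<->"` (or `"<=>"`) marks a
#' reversible reaction. An empty side denotes an exchange with the
#' environment.
#'
#' @param eq equation string.
#' @return List with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<->|<=>", eq)) "<->" else "->"
  reversible <- arrow == "<->"
  parts <- strsplit(eq, "<->|<=>|->")[[1]]
  if (length(parts) > 2) stop(sprintf("malformed equation: '%s'", eq))
  lhs <- if (length(parts) >= 1) trimws(parts[1]) else ""
  rhs <- if (length(parts) == 2) trimws(parts[2]) else ""
  parse_side <- function(side, sign) {
    if (side == "") return(numeric())
    if (grepl("^\\+|\\+$", side)) {
      stop(sprintf("malformed equation side '%s' in '%s'", side, eq))
    }
    terms <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric()
    for (tm in terms) {
      if (tm == "") stop(sprintf("malformed equation term in '%s'", eq))
      tok <- strsplit(tm, "\\s+")[[1]]
      if (length(tok) == 1) {
        coef <- 1; met <- tok
      } else if (length(tok) == 2 && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        coef <- as.numeric(tok[1]); met <- tok[2]
      } else {
        stop(sprintf("malformed equation term '%s' in '%s'", tm, eq))
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  l <- parse_side(lhs, -1)
  r <- parse_side(rhs, +1)
  st <- l
  for (met in names(r)) st[met] <- (if (met %in% names(st)) st[met] else 0) + r[met]
  st <- st[st != 0]
  list(stoich = st, reversible = reversible)
}

#' Format a stoichiometry vector as an equation string
#' @param stoich named numeric vector of coefficients.
#' @param reversible logical.
#' @return Equation string in the `"A + 2 B -> C"` dialect.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(vapply(names(v), function(m) {
      if (v[m] == 1) m else paste(format(unname(v[m])), m)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(-stoich[stoich < 0])
  rhs <- fmt(stoich[stoich > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

#' Parse an AND/OR gene rule into isoenzyme arms
#'
#' Returns a list with one character vector per OR-branch (isoenzyme arm);
#' genes inside a branch are AND-ed (complex subunits). An empty rule gives
#' an empty list.
#'
#' @param rule gene rule string, e.g. `"HXK1 or HXK2"`, `"(PDA1 and PDB1)"`.
#' @return List of character vectors.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(list())
  # split on 'or' at parenthesis depth zero
  chars <- strsplit(rule, "")[[1]]
  depth <- 0
  cut <- integer()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth == 0 && (ch == "o" || ch == "O") && i + 1 <= length(chars) &&
        tolower(chars[i + 1]) == "r" &&
        (i == 1 || chars[i - 1] %in% c(" ", ")")) &&
        (i + 2 > length(chars) || chars[i + 2] %in% c(" ", "("))) {
      cut <- c(cut, i)
      i <- i + 2
    } else i <- i + 1
  }
  starts <- c(1, cut + 2)
  ends <- c(cut - 1, length(chars))
  arms <- mapply(function(s, e) paste(chars[s:e], collapse = ""), starts, ends)
  lapply(arms, function(a) {
    a <- gsub("[()]", " ", a)
    toks <- strsplit(trimws(a), "\\s+(and|AND|And)\\s+|\\s+")[[1]]
    toks <- toks[nzchar(toks) & !tolower(toks) %in% c("and", "or")]
    toks
  })
}

.rxn_cols <- c("id", "lb", "ub", "reversible", "gene_rule", "subsystem")

#' Load a stoichiometric model from disk
#'
#' Dialects:
#' \describe{
#'   \item{`native-tsv`}{`path` is a directory holding `metabolites.tsv`
#'     (columns id, name, compartment) and `reactions.tsv` (columns id,
#'     equation, lb, ub, gene_rule, subsystem, and optionally objective).}
#'   \item{`native-json`}{single JSON file with a `format_version` field.}
#'   \item{`sbml`}{read-only basic SBML ingest (species, reactions,
#'     reversibility); requires \pkg{xml2}.}
#' }
#' Unknown fields in the native dialects are ignored with a warning.
#'
#' @param path file or directory path depending on dialect.
#' @param dialect one of `"native-tsv"`, `"native-json"`, `"sbml"`.
#' @return A validated `stoich_model`.
#' @export
load_stoich_model <- function(path,
                              dialect = c("native-tsv", "native-json", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "native-tsv" = .load_model_tsv(path),
         "native-json" = .load_model_json(path),
         "sbml" = .load_model_sbml(path))
}

.load_model_tsv <- function(dir) {
  mfile <- file.path(dir, "metabolites.tsv")
  rfile <- file.path(dir, "reactions.tsv")
  if (!file.exists(mfile) || !file.exists(rfile)) {
    stop(sprintf("expected metabolites.tsv and reactions.tsv under '%s'", dir))
  }
  mets <- utils::read.delim(mfile, stringsAsFactors = FALSE)
  rx <- utils::read.delim(rfile, stringsAsFactors = FALSE)
  known_m <- c("id", "name", "compartment")
  known_r <- c("id", "equation", "lb", "ub", "gene_rule", "subsystem", "objective")
  extra <- c(setdiff(names(mets), known_m), setdiff(names(rx), known_r))
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  need <- setdiff(c("id", "equation", "lb", "ub"), names(rx))
  if (length(need)) stop(sprintf("reactions.tsv lacks column(s): %s",
                                 paste(need, collapse = ", ")))
  if (is.null(rx$gene_rule)) rx$gene_rule <- ""
  if (is.null(rx$subsystem)) rx$subsystem <- ""
  rx$gene_rule[is.na(rx$gene_rule)] <- ""
  rx$subsystem[is.na(rx$subsystem)] <- ""
  stoich <- list()
  reversible <- logical(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    p <- tryCatch(parse_equation(rx$equation[i]), error = function(e) {
      stop(sprintf("reactions.tsv record %d ('%s'): %s", i, rx$id[i],
                   conditionMessage(e)))
    })
    stoich[[rx$id[i]]] <- p$stoich
    reversible[i] <- p$reversible
  }
  genes <- unique(unlist(lapply(rx$gene_rule, function(g) unlist(parse_gene_rule(g)))))
  if (is.null(genes)) genes <- character()
  objective <- .default_objective(rx)
  reactions <- data.frame(id = rx$id, lb = as.numeric(rx$lb),
                          ub = as.numeric(rx$ub), reversible = reversible,
                          gene_rule = rx$gene_rule, subsystem = rx$subsystem,
                          stringsAsFactors = FALSE)
  stoich_model(mets[, intersect(known_m, names(mets))], reactions, stoich,
               genes, objective)
}

.default_objective <- function(rx) {
  if (!is.null(rx$objective)) {
    w <- which(!is.na(rx$objective) & rx$objective != 0)
    return(stats::setNames(as.numeric(rx$objective[w]), rx$id[w]))
  }
  bio <- grep("biomass|growth", rx$id, ignore.case = TRUE, value = TRUE)
  if (length(bio) == 1) return(stats::setNames(1, bio))
  numeric()
}

.load_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$format_version)) stop("JSON model lacks 'format_version'")
  known <- c("format_version", "metabolites", "reactions", "genes", "objective")
  extra <- setdiff(names(j), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown JSON field(s): %s",
                    paste(extra, collapse = ", ")))
  }
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c", stringsAsFactors = FALSE)
  }))
  stoich <- list()
  rows <- lapply(j$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    stoich[[r$id]] <<- st
    data.frame(id = r$id, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
               reversible = as.numeric(r$lb) < 0,
               gene_rule = r$gene_rule %||% "",
               subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)
  })
  reactions <- do.call(rbind, rows)
  objective <- unlist(j$objective) %||% numeric()
  genes <- unlist(j$genes) %||% character()
  stoich_model(mets, reactions, stoich, genes, objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML ingest requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  boundary_ids <- mets$id[boundary]
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  stoich <- list()
  rows <- lapply(rxns, function(r) {
    id <- xml2::xml_attr(r, "id")
    rev <- !(xml2::xml_attr(r, "reversible") %in% c("false", "0"))
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(r, sprintf("./%s/speciesReference", tag))
      if (!length(refs)) return(numeric())
      s <- xml2::xml_attr(refs, "stoichiometry")
      s[is.na(s)] <- "1"
      stats::setNames(sign * as.numeric(s), xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    st <- st[!names(st) %in% boundary_ids]
    stoich[[id]] <<- st
    data.frame(id = id, lb = if (rev) -1000 else 0, ub = 1000,
               reversible = rev, gene_rule = "", subsystem = "",
               stringsAsFactors = FALSE)
  })
  reactions <- do.call(rbind, rows)
  mets <- mets[!boundary, , drop = FALSE]
  stoich_model(mets, reactions, stoich, character(), numeric())
}

#' Write a stoichiometric model to disk
#'
#' @param model a `stoich_model`.
#' @param path directory (`native-tsv`) or file path (`native-json`).
#' @param dialect `"native-tsv"` or `"native-json"`.
#' @return `path`, invisibly.
#' @export
write_stoich_model <- function(model, path,
                               dialect = c("native-tsv", "native-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "native-tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rx <- model$reactions
    eq <- vapply(rx$id, function(rid) {
      format_equation(model$stoich[[rid]], rx$reversible[rx$id == rid])
    }, character(1))
    obj <- rep(0, nrow(rx))
    obj[match(names(model$objective), rx$id)] <- model$objective
    out <- data.frame(id = rx$id, equation = eq, lb = rx$lb, ub = rx$ub,
                      gene_rule = rx$gene_rule, subsystem = rx$subsystem,
                      objective = obj, stringsAsFactors = FALSE)
    utils::write.table(out, file.path(path, "reactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    j <- list(
      format_version = 1L,
      metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
        as.list(model$metabolites[i, ])
      }),
      reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
        r <- model$reactions[i, ]
        list(id = r$id, lb = r$lb, ub = r$ub, gene_rule = r$gene_rule,
             subsystem = r$subsystem,
             stoichiometry = as.list(model$stoich[[r$id]]))
      }),
      genes = model$genes,
      objective = as.list(model$objective))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Construct an enzyme annotation table
#'
#' One row per (enzyme, reaction) pair, mirroring the `enzymes.tsv` layout:
#' columns `enzyme_id`, `gene`, `mw_g_per_mmol`, `reaction_id`, `kcat_per_h`,
#' `complex_id`, `arm_id`. A reaction annotated with genes but lacking a kcat
#' carries an explicit `NA` kcat marker (and is left unconstrained by the
#' enzyme-constraint transformation); silent defaulting is not allowed.
#'
#' @param df data.frame in the layout above.
#' @return Object of class `enzyme_table`.
#' @export
enzyme_table <- function(df) {
  need <- c("enzyme_id", "gene", "mw_g_per_mmol", "reaction_id", "kcat_per_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("enzyme table lacks column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (is.null(df$complex_id)) df$complex_id <- rep(NA_character_, nrow(df))
  if (is.null(df$arm_id)) df$arm_id <- rep(NA_character_, nrow(df))
  bad <- !is.na(df$kcat_per_h) & df$kcat_per_h <= 0
  if (any(bad)) {
    stop(sprintf("non-positive kcat for: %s",
                 paste(unique(df$enzyme_id[bad]), collapse = ", ")))
  }
  mw <- unique(df[, c("enzyme_id", "mw_g_per_mmol")])
  if (anyDuplicated(mw$enzyme_id)) {
    stop("inconsistent molecular weight for an enzyme across rows")
  }
  structure(as.data.frame(df), class = c("enzyme_table", "data.frame"))
}

#' Read an enzyme annotation table from `enzymes.tsv`
#' @param path path to a TSV file (or a directory containing `enzymes.tsv`).
#' @return An `enzyme_table`.
#' @export
read_enzyme_table <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "enzymes.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  enzyme_table(df)
}

#' Write an enzyme annotation table
#' @param enzymes an `enzyme_table`.
#' @param path output TSV path (or directory).
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(enzymes, path) {
  if (dir.exists(path)) path <- file.path(path, "enzymes.tsv")
  utils::write.table(as.data.frame(enzymes), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("stoich_model: %d metabolites, %d reactions, %d genes\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  invisible(x)
}
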