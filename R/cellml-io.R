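# Reading and writing the flat CellML-style document subset.
#
# Supported documents are CellML 1.0-like: <model> containing <units>
# definitions, <component>s with <variable>s and content-MathML <math>
# equations, <connection>s mapping variables between components, and embedded
# RDF annotations.  Imports (CellML 1.1) are not supported.  Numeric
# constants in equations are kept as `cn_(value, "units")` calls so their
# declared units survive until units standardization.

NS_MATHML <- "http://www.w3.org/1998/Math/MathML"

# Placeholder for a units-carrying numeric constant inside raw equations.
#' @noRd
cn_ <- function(value, units) value

#' Conversion failure condition
#' @noRd
conversion_failure <- function(category, location, message) {
  structure(
    class = c("myo_conversion_failure", "error", "condition"),
    list(message = sprintf("[%s] %s: %s", category, location, message),
         category = category, location = location, detail = message,
         call = NULL)
  )
}

#' Build a conversion report
#'
#' @param failures list of failure records (category, location, message).
#' @return object of class `conversion_report` with `status` "ok" or "failed".
#' @export
conversion_report <- function(failures = list()) {
  structure(list(status = if (length(failures) == 0L) "ok" else "failed",
                 failures = failures),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("Conversion report:", x$status, "\n")
  for (f in x$failures) {
    cat(sprintf("  - [%s] %s: %s\n", f$category, f$location, f$message))
  }
  invisible(x)
}

#' @export
format.conversion_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
}

fail_record <- function(category, location, message) {
  list(category = category, location = location, message = message)
}

# ---------------------------------------------------------------------------
# MathML parsing

.mathml_unary <- c(exp = "exp", ln = "log", abs = "abs", floor = "floor",
                   ceiling = "ceiling", tanh = "tanh")
.mathml_rel <- c(lt = "<", gt = ">", leq = "<=", geq = ">=", eq = "==", neq = "!=")

parse_mathml_expr <- function(node, where) {
  name <- xml2::xml_name(node)
  if (name == "ci") {
    return(as.symbol(trimws(xml2::xml_text(node))))
  }
  if (name == "cn") {
    units <- xml2::xml_attr(node, "units")
    kids <- xml2::xml_children(node)
    if (length(kids) > 0L && any(xml2::xml_name(kids) == "sep")) {
      txt <- strsplit(xml2::xml_text(node), "[[:space:]]+")[[1]]
      txt <- txt[nzchar(txt)]
      val <- as.numeric(txt[1]) * 10^as.numeric(txt[2])
    } else {
      val <- as.numeric(trimws(xml2::xml_text(node)))
    }
    if (is.na(units) || !nzchar(units)) {
      stop(conversion_failure("invalid-units", where,
                              sprintf("numeric constant %s lacks units", format(val))))
    }
    return(call("cn_", val, units))
  }
  if (name == "piecewise") {
    args <- list()
    for (child in xml2::xml_children(node)) {
      cn <- xml2::xml_name(child)
      parts <- xml2::xml_children(child)
      if (cn == "piece") {
        val <- parse_mathml_expr(parts[[1]], where)
        cond <- parse_mathml_expr(parts[[2]], where)
        args <- c(args, list(cond, val))
      } else if (cn == "otherwise") {
        args <- c(args, list(parse_mathml_expr(parts[[1]], where)))
      } else {
        stop(conversion_failure("unsupported-construct", where,
                                sprintf("unsupported element <%s> in piecewise", cn)))
      }
    }
    # move a trailing otherwise to the end (it is parsed in document order)
    return(as.call(c(as.symbol("piecewise_"), args)))
  }
  if (name != "apply") {
    stop(conversion_failure("unsupported-construct", where,
                            sprintf("unsupported MathML element <%s>", name)))
  }
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args_nodes <- kids[-1L]
  if (op == "diff") {
    stop(conversion_failure("unsupported-construct", where,
                            "<diff> only supported on the left of a top-level equation"))
  }
  nary <- function(fn, nodes) {
    exprs <- lapply(nodes, parse_mathml_expr, where = where)
    Reduce(function(a, b) call(fn, a, b), exprs)
  }
  if (op == "plus") {
    if (length(args_nodes) == 1L) return(parse_mathml_expr(args_nodes[[1]], where))
    return(nary("+", args_nodes))
  }
  if (op == "minus") {
    if (length(args_nodes) == 1L) {
      return(call("-", parse_mathml_expr(args_nodes[[1]], where)))
    }
    return(nary("-", args_nodes))
  }
  if (op == "times") return(nary("*", args_nodes))
  if (op == "divide") return(nary("/", args_nodes))
  if (op == "power") return(nary("^", args_nodes))
  if (op == "root") {
    degree <- 2
    vals <- list()
    for (nd in args_nodes) {
      if (xml2::xml_name(nd) == "degree") {
        degree <- as.numeric(xml2::xml_text(nd))
      } else {
        vals <- c(vals, list(parse_mathml_expr(nd, where)))
      }
    }
    if (degree == 2) return(call("sqrt", vals[[1]]))
    return(call("^", vals[[1]], 1 / degree))
  }
  if (op == "log") {
    base <- 10
    vals <- list()
    for (nd in args_nodes) {
      if (xml2::xml_name(nd) == "logbase") {
        base <- as.numeric(xml2::xml_text(nd))
      } else {
        vals <- c(vals, list(parse_mathml_expr(nd, where)))
      }
    }
    if (base == 10) return(call("log10", vals[[1]]))
    return(call("/", call("log", vals[[1]]), log(base)))
  }
  if (op %in% names(.mathml_unary)) {
    return(call(.mathml_unary[[op]], parse_mathml_expr(args_nodes[[1]], where)))
  }
  if (op %in% names(.mathml_rel)) {
    return(nary(.mathml_rel[[op]], args_nodes))
  }
  if (op == "and") return(nary("&", args_nodes))
  if (op == "or") return(nary("|", args_nodes))
  if (op == "not") return(call("!", parse_mathml_expr(args_nodes[[1]], where)))
  stop(conversion_failure("unsupported-construct", where,
                          sprintf("unsupported MathML operator <%s>", op)))
}

parse_equation <- function(apply_node, where) {
  kids <- xml2::xml_children(apply_node)
  if (xml2::xml_name(kids[[1]]) != "eq") {
    stop(conversion_failure("unsupported-construct", where,
                            "top-level MathML must be an <eq> application"))
  }
  lhs <- kids[[2]]
  rhs <- parse_mathml_expr(kids[[3]], where)
  if (xml2::xml_name(lhs) == "apply" &&
      xml2::xml_name(xml2::xml_child(lhs, 1)) == "diff") {
    lkids <- xml2::xml_children(lhs)
    bvar <- NULL
    target <- NULL
    for (nd in lkids[-1L]) {
      if (xml2::xml_name(nd) == "bvar") {
        bvar <- trimws(xml2::xml_text(nd))
      } else if (xml2::xml_name(nd) == "ci") {
        target <- trimws(xml2::xml_text(nd))
      }
    }
    if (is.null(bvar) || is.null(target)) {
      stop(conversion_failure("unsupported-construct", where,
                              "<diff> requires one <bvar> and one <ci>"))
    }
    return(list(kind = "ode", target = target, bvar = bvar, rhs = rhs))
  }
  if (xml2::xml_name(lhs) == "ci") {
    return(list(kind = "assign", target = trimws(xml2::xml_text(lhs)), rhs = rhs))
  }
  stop(conversion_failure("unsupported-construct", where,
                          "equation left-hand side must be <ci> or a derivative"))
}

# ---------------------------------------------------------------------------
# Document parsing

#' Parse a flat CellML-subset document
#'
#' Reads components, variables (with units and optional initial values),
#' content-MathML equations, unit definitions, connections and RDF triples.
#' Unsupported constructs raise classed conditions
#' (`myo_conversion_failure`) carrying a failure category; use
#' [convert_cellml()] for a non-throwing interface that collects failures
#' into a [conversion_report()].
#'
#' @param xml_text document text (or an `xml_document`).
#' @return an object of class `raw_model`.
#' @export
parse_document <- function(xml_text) {
  doc <- if (inherits(xml_text, "xml_document")) xml_text else xml2::read_xml(xml_text)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "model") {
    stop(conversion_failure("unsupported-construct", "document",
                            sprintf("root element is <%s>, expected <model>",
                                    xml2::xml_name(root))))
  }
  model_name <- xml2::xml_attr(root, "name")
  model_id <- xml2::xml_attr(root, "id")
  unit_defs <- list()
  components <- list()
  connections <- list()
  triples <- list()

  for (node in xml2::xml_children(root)) {
    nm <- xml2::xml_name(node)
    if (nm == "units") {
      uname <- xml2::xml_attr(node, "name")
      parts <- lapply(xml2::xml_children(node), function(p) {
        list(units = xml2::xml_attr(p, "units"),
             prefix = xml2::xml_attr(p, "prefix"),
             exponent = xml2::xml_attr(p, "exponent"),
             multiplier = xml2::xml_attr(p, "multiplier"))
      })
      unit_defs[[uname]] <- parts
    } else if (nm == "component") {
      cname <- xml2::xml_attr(node, "name")
      vars <- list()
      eqs <- list()
      for (child in xml2::xml_children(node)) {
        cn <- xml2::xml_name(child)
        if (cn == "variable") {
          vname <- xml2::xml_attr(child, "name")
          iv <- xml2::xml_attr(child, "initial_value")
          vars[[vname]] <- list(
            name = vname,
            units = xml2::xml_attr(child, "units"),
            initial_value = if (is.na(iv)) NA_real_ else as.numeric(iv),
            interface = xml2::xml_attr(child, "public_interface"),
            id = xml2::xml_attr(child, "id")
          )
        } else if (cn == "math") {
          for (eqnode in xml2::xml_children(child)) {
            eqs[[length(eqs) + 1L]] <-
              parse_equation(eqnode, sprintf("component '%s'", cname))
          }
        } else {
          stop(conversion_failure("unsupported-construct",
                                  sprintf("component '%s'", cname),
                                  sprintf("unsupported element <%s>", cn)))
        }
      }
      components[[cname]] <- list(name = cname, variables = vars, equations = eqs)
    } else if (nm == "connection") {
      comp1 <- comp2 <- NULL
      maps <- list()
      for (child in xml2::xml_children(node)) {
        if (xml2::xml_name(child) == "map_components") {
          comp1 <- xml2::xml_attr(child, "component_1")
          comp2 <- xml2::xml_attr(child, "component_2")
        } else if (xml2::xml_name(child) == "map_variables") {
          maps[[length(maps) + 1L]] <-
            c(xml2::xml_attr(child, "variable_1"), xml2::xml_attr(child, "variable_2"))
        }
      }
      for (mv in maps) {
        connections[[length(connections) + 1L]] <-
          list(component_1 = comp1, variable_1 = mv[[1]],
               component_2 = comp2, variable_2 = mv[[2]])
      }
    } else if (nm == "RDF") {
      triples <- c(triples, parse_rdf(node))
    } else {
      stop(conversion_failure("unsupported-construct", "model",
                              sprintf("unsupported element <%s>", nm)))
    }
  }
  structure(list(name = model_name, id = model_id, unit_definitions = unit_defs,
                 components = components, connections = connections,
                 annotations = triples),
            class = "raw_model")
}

# RDF/XML subset: <rdf:Description rdf:about="#id"> with either
# rdf:resource-valued or literal-valued property elements.
parse_rdf <- function(rdf_node) {
  triples <- list()
  for (desc in xml2::xml_children(rdf_node)) {
    if (xml2::xml_name(desc) != "Description") next
    subject <- xml2::xml_attr(desc, "about")
    for (prop in xml2::xml_children(desc)) {
      pred <- xml2::xml_name(prop)
      res <- xml2::xml_attr(prop, "resource")
      obj <- if (!is.na(res)) local_name(res) else trimws(xml2::xml_text(prop))
      triples[[length(triples) + 1L]] <-
        list(subject = sub("^#", "", subject), predicate = pred, object = obj)
    }
  }
  triples
}

local_name <- function(uri) sub("^.*[#/]", "", uri)

# ---------------------------------------------------------------------------
# Flattening

#' Flatten a multi-component model into a single namespace
#'
#' Variables joined by connections are merged to one canonical symbol and all
#' equations are rewritten in terms of canonical symbols.  The accompanying
#' report records over-constrained variables (two defining equations),
#' missing parameters (no definition and no initial value) and
#' under-constrained states (rate equation but no initial value).
#'
#' @param raw a `raw_model` from [parse_document()].
#' @return list with `variables` (per canonical symbol: units, initial value,
#'   annotation ids), `assignments` (topologically ordered), `odes`,
#'   `time_var`, `unit_table`, and `report`.
#' @export
flatten <- function(raw) {
  failures <- list()
  # resolve units table
  utab <- base_unit_table()
  utab$millisecond <- unit_scale(utab$second, 1e-3)
  utab$millivolt <- unit_scale(utab$volt, 1e-3)
  # user definitions may reference each other in order
  for (nm in names(raw$unit_definitions)) {
    u <- tryCatch(compose_unit(raw$unit_definitions[[nm]], utab),
                  error = function(e) e)
    if (inherits(u, "error")) {
      failures[[length(failures) + 1L]] <-
        fail_record("invalid-units", sprintf("units '%s'", nm), conditionMessage(u))
    } else {
      utab[[nm]] <- u
    }
  }

  # variable table keyed by component.name
  key <- function(comp, var) paste(comp, var, sep = ".")
  vtab <- list()
  for (comp in raw$components) {
    for (v in comp$variables) {
      vtab[[key(comp$name, v$name)]] <- c(v, list(component = comp$name))
    }
  }
  # union-find over connections
  parent <- stats::setNames(names(vtab), names(vtab))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (conn in raw$connections) {
    k1 <- key(conn$component_1, conn$variable_1)
    k2 <- key(conn$component_2, conn$variable_2)
    if (is.null(vtab[[k1]]) || is.null(vtab[[k2]])) {
      missing_k <- if (is.null(vtab[[k1]])) k1 else k2
      failures[[length(failures) + 1L]] <-
        fail_record("under-constrained", "connection",
                    sprintf("connection endpoint '%s' does not exist", missing_k))
      next
    }
    parent[[find(k1)]] <- find(k2)
  }
  groups <- split(names(vtab), vapply(names(vtab), find, ""))

  # canonical naming: bare variable name when unambiguous, component__name
  # otherwise; deterministic by sorting group representatives
  base_names <- vapply(groups, function(g) vtab[[g[[1]]]]$name, "")
  canon <- character(length(groups))
  for (i in seq_along(groups)) {
    nm <- base_names[[i]]
    if (sum(base_names == nm) == 1L) {
      canon[[i]] <- nm
    } else {
      rep_key <- sort(groups[[i]])[[1]]
      canon[[i]] <- paste(vtab[[rep_key]]$component, vtab[[rep_key]]$name, sep = "__")
    }
  }
  member_to_canon <- character(0)
  for (i in seq_along(groups)) {
    for (k in groups[[i]]) member_to_canon[[k]] <- canon[[i]]
  }

  # merged variable records
  variables <- list()
  for (i in seq_along(groups)) {
    members <- lapply(groups[[i]], function(k) vtab[[k]])
    ivs <- stats::na.omit(vapply(members, function(m) m$initial_value, 1))
    ids <- vapply(members, function(m) m$id, "")
    ids <- ids[!is.na(ids) & nzchar(ids)]
    units_str <- members[[1]]$units
    u <- tryCatch(resolve_unit(units_str, utab), error = function(e) e)
    if (inherits(u, "error")) {
      failures[[length(failures) + 1L]] <-
        fail_record("invalid-units", sprintf("variable '%s'", canon[[i]]),
                    conditionMessage(u))
      u <- unit_new(1)
    }
    variables[[canon[[i]]]] <- list(
      name = canon[[i]], units = units_str, unit = u,
      initial_value = if (length(ivs) > 0L) ivs[[1]] else NA_real_,
      ids = ids
    )
  }

  # rewrite equations with canonical symbols
  rewrite_expr <- function(e, comp) {
    if (is.symbol(e)) {
      k <- key(comp, as.character(e))
      if (!is.null(vtab[[k]])) return(as.symbol(member_to_canon[[k]]))
      return(e)
    }
    if (is.call(e)) {
      if (is_call_to(e, "cn_")) return(e)
      for (i in seq_along(e)[-1L]) e[[i]] <- rewrite_expr(e[[i]], comp)
    }
    e
  }
  assignments <- list()
  odes <- list()
  time_vars <- character(0)
  for (comp in raw$components) {
    for (eq in comp$equations) {
      tk <- key(comp$name, eq$target)
      if (is.null(vtab[[tk]])) {
        failures[[length(failures) + 1L]] <-
          fail_record("under-constrained", sprintf("component '%s'", comp$name),
                      sprintf("equation defines undeclared variable '%s'", eq$target))
        next
      }
      target <- member_to_canon[[tk]]
      rhs <- rewrite_expr(eq$rhs, comp$name)
      undeclared <- setdiff(expr_free_vars(rhs), c(names(variables), "cn_"))
      for (ud in undeclared) {
        failures[[length(failures) + 1L]] <-
          fail_record("under-constrained", sprintf("component '%s'", comp$name),
                      sprintf("equation references undeclared variable '%s'", ud))
      }
      if (eq$kind == "ode") {
        bk <- key(comp$name, eq$bvar)
        if (!is.null(vtab[[bk]])) time_vars <- c(time_vars, member_to_canon[[bk]])
        odes[[length(odes) + 1L]] <- list(state = target, rhs = rhs)
      } else {
        assignments[[length(assignments) + 1L]] <- list(var = target, rhs = rhs)
      }
    }
  }
  time_var <- if (length(time_vars) > 0L) unique(time_vars)[[1]] else NA_character_

  # constraint accounting
  def_count <- stats::setNames(integer(length(variables)), names(variables))
  for (a in assignments) def_count[[a$var]] <- def_count[[a$var]] + 1L
  for (o in odes) def_count[[o$state]] <- def_count[[o$state]] + 1L
  ode_states <- vapply(odes, function(o) o$state, "")
  used <- unique(c(unlist(lapply(assignments, function(a) expr_free_vars(a$rhs))),
                   unlist(lapply(odes, function(o) expr_free_vars(o$rhs))),
                   vapply(assignments, function(a) a$var, ""), ode_states))
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (def_count[[nm]] > 1L) {
      failures[[length(failures) + 1L]] <-
        fail_record("over-constrained", sprintf("variable '%s'", nm),
                    sprintf("%d defining equations for one variable", def_count[[nm]]))
    }
    if (def_count[[nm]] == 0L && is.na(v$initial_value) &&
        !identical(nm, time_var)) {
      failures[[length(failures) + 1L]] <-
        fail_record("missing-parameter", sprintf("variable '%s'", nm),
                    "no defining equation and no initial value")
    }
    if (nm %in% ode_states && is.na(v$initial_value)) {
      failures[[length(failures) + 1L]] <-
        fail_record("under-constrained", sprintf("variable '%s'", nm),
                    "state variable has no initial value")
    }
  }

  # topological ordering of assignments (ties by variable name)
  if (length(assignments) > 0L) {
    anames <- vapply(assignments, function(a) a$var, "")
    deps <- lapply(assignments, function(a) intersect(expr_free_vars(a$rhs), anames))
    ordered <- character(0)
    remaining <- order(anames)
    while (length(remaining) > 0L) {
      ready <- remaining[vapply(remaining, function(i) {
        all(deps[[i]] %in% ordered)
      }, TRUE)]
      if (length(ready) == 0L) {
        failures[[length(failures) + 1L]] <-
          fail_record("over-constrained", "equations",
                      sprintf("cyclic dependency among: %s",
                              paste(sort(anames[remaining]), collapse = ", ")))
        ordered <- c(ordered, anames[remaining])
        remaining <- integer(0)
      } else {
        ready <- ready[order(anames[ready])]
        ordered <- c(ordered, anames[ready])
        remaining <- setdiff(remaining, ready)
      }
    }
    assignments <- assignments[match(ordered, anames)]
  }

  list(variables = variables, assignments = assignments, odes = odes,
       time_var = time_var, unit_table = utab,
       report = conversion_report(failures))
}

# ---------------------------------------------------------------------------
# Annotations

# Default accepted predicates for "is"-style term annotations; the relation
# matters, not the URI, so this list is configurable.
default_is_predicates <- function() c("is", "isVersionOf", "pycml_is")

#' Read ontology annotations from a raw model
#'
#' Resolves RDF triples against variables by in-document id and returns
#' per-variable term sets, role flags, range-check bounds and model-level
#' flags (notably whether the model is self-excitatory, in which case no
#' stimulus current is expected).
#'
#' @param raw a `raw_model`.
#' @param flat optional flattened form (computed if missing).
#' @param is_predicates predicate local names accepted for term annotation.
#' @return list with `terms` (canonical variable -> character vector),
#'   `modifiable`, `derived` (character vectors of variable names), `ranges`
#'   (variable -> c(lo, hi)), `self_excitatory` (flag), `warnings`.
#' @export
read_annotations <- function(raw, flat = NULL,
                             is_predicates = default_is_predicates()) {
  if (is.null(flat)) flat <- flatten(raw)
  id_to_var <- character(0)
  for (v in flat$variables) {
    for (id in v$ids) id_to_var[[id]] <- v$name
  }
  terms <- list()
  modifiable <- character(0)
  derived <- character(0)
  ranges <- list()
  self_excitatory <- FALSE
  warnings <- character(0)
  model_ids <- c(raw$id, raw$name)
  for (tr in raw$annotations) {
    subj <- tr$subject
    if (subj %in% names(id_to_var)) {
      var <- id_to_var[[subj]]
      if (tr$predicate %in% is_predicates) {
        terms[[var]] <- unique(c(terms[[var]], tr$object))
      } else if (tr$predicate == "modifiable-parameter" &&
                 tolower(tr$object) %in% c("yes", "true")) {
        modifiable <- c(modifiable, var)
      } else if (tr$predicate == "derived-quantity" &&
                 tolower(tr$object) %in% c("yes", "true")) {
        derived <- c(derived, var)
      } else if (tr$predicate == "range-low") {
        r <- ranges[[var]] %||% c(-Inf, Inf)
        r[1] <- as.numeric(tr$object)
        ranges[[var]] <- r
      } else if (tr$predicate == "range-high") {
        r <- ranges[[var]] %||% c(-Inf, Inf)
        r[2] <- as.numeric(tr$object)
        ranges[[var]] <- r
      } else {
        warnings <- c(warnings,
                      sprintf("ignored annotation predicate '%s' on '%s'",
                              tr$predicate, var))
      }
    } else if (!is.na(subj) && subj %in% model_ids) {
      if (tr$predicate == "is-self-excitatory" &&
          tolower(tr$object) %in% c("yes", "true")) {
        self_excitatory <- TRUE
      }
    } else {
      warnings <- c(warnings,
                    sprintf("annotation subject '#%s' matches no variable; triple ignored",
                            subj))
    }
  }
  list(terms = terms, modifiable = unique(modifiable), derived = unique(derived),
       ranges = ranges, self_excitatory = self_excitatory, warnings = warnings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Writing

serialize_mathml <- function(e) {
  if (is_const(e)) {
    return(sprintf('<cn units="dimensionless">%s</cn>',
                   format(e, digits = 17)))
  }
  if (is.symbol(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  stopifnot(is.call(e))
  fn <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  if (fn == "cn_") {
    return(sprintf('<cn units="%s">%s</cn>', args[[2L]],
                   format(args[[1L]], digits = 17)))
  }
  if (fn == "(") return(serialize_mathml(args[[1L]]))
  if (fn == "piecewise_") {
    n <- length(args)
    npair <- n %/% 2L
    parts <- character(0)
    for (k in seq_len(npair)) {
      parts <- c(parts, sprintf("<piece>%s%s</piece>",
                                serialize_mathml(args[[2L * k]]),
                                serialize_mathml(args[[2L * k - 1L]])))
    }
    if (n %% 2L == 1L) {
      parts <- c(parts, sprintf("<otherwise>%s</otherwise>",
                                serialize_mathml(args[[n]])))
    }
    return(sprintf("<piecewise>%s</piecewise>", paste(parts, collapse = "")))
  }
  opmap <- c("+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
             "^" = "power", exp = "exp", log = "ln", log10 = "log",
             sqrt = "root", abs = "abs", floor = "floor", ceiling = "ceiling",
             tanh = "tanh", "<" = "lt", ">" = "gt", "<=" = "leq", ">=" = "geq",
             "==" = "eq", "!=" = "neq", "&" = "and", "|" = "or", "!" = "not")
  if (!fn %in% names(opmap)) {
    stop("cannot serialize operator '", fn, "' to MathML", call. = FALSE)
  }
  inner <- paste(vapply(args, serialize_mathml, ""), collapse = "")
  sprintf("<apply><%s/>%s</apply>", opmap[[fn]], inner)
}

#' Write a flat model as a CellML-subset document
#'
#' Inverse of [parse_document()] + [flatten()] for single-component models:
#' `flatten(parse_document(write_document(m, a)))` reproduces the flat
#' equation set up to equation ordering.
#'
#' @param flat flat model as produced by [flatten()] (or a fixture builder).
#' @param annotations annotation structure as from [read_annotations()], or a
#'   list of raw triples under `$triples`.
#' @param name model name.
#' @param unit_definitions named list of unit definition part-lists to emit.
#' @return document text (character scalar).
#' @export
write_document <- function(flat, annotations = NULL, name = "model",
                           unit_definitions = list()) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<model name="%s" id="%s" xmlns="http://www.cellml.org/cellml/1.0#" ',
                            'xmlns:cmeta="http://www.cellml.org/metadata/1.0#">'),
                     name, name))
  for (unm in names(unit_definitions)) {
    parts <- unit_definitions[[unm]]
    inner <- vapply(parts, function(p) {
      at <- sprintf(' units="%s"', p$units)
      if (!is.null(p$prefix) && !is.na(p$prefix) && nzchar(p$prefix)) {
        at <- paste0(at, sprintf(' prefix="%s"', p$prefix))
      }
      if (!is.null(p$exponent) && !is.na(p$exponent) && nzchar(p$exponent)) {
        at <- paste0(at, sprintf(' exponent="%s"', p$exponent))
      }
      if (!is.null(p$multiplier) && !is.na(p$multiplier) && nzchar(p$multiplier)) {
        at <- paste0(at, sprintf(' multiplier="%s"', p$multiplier))
      }
      sprintf("  <unit%s/>", at)
    }, "")
    lines <- c(lines, sprintf('<units name="%s">', unm), inner, "</units>")
  }
  lines <- c(lines, '<component name="main">')
  for (v in flat$variables) {
    at <- sprintf(' name="%s" units="%s"', v$name, v$units)
    if (!is.na(v$initial_value)) {
      at <- paste0(at, sprintf(' initial_value="%s"',
                               format(v$initial_value, digits = 17)))
    }
    id <- if (length(v$ids) > 0L) v$ids[[1]] else v$name
    at <- paste0(at, sprintf(' id="%s"', id))
    lines <- c(lines, sprintf("  <variable%s/>", at))
  }
  lines <- c(lines, sprintf('  <math xmlns="%s">', NS_MATHML))
  for (a in flat$assignments) {
    lines <- c(lines, sprintf("    <apply><eq/><ci>%s</ci>%s</apply>",
                              a$var, serialize_mathml(a$rhs)))
  }
  tv <- if (!is.na(flat$time_var)) flat$time_var else "time"
  for (o in flat$odes) {
    lhs <- sprintf("<apply><diff/><bvar><ci>%s</ci></bvar><ci>%s</ci></apply>",
                   tv, o$state)
    lines <- c(lines, sprintf("    <apply><eq/>%s%s</apply>",
                              lhs, serialize_mathml(o$rhs)))
  }
  lines <- c(lines, "  </math>", "</component>")

  triples <- annotations_to_triples(flat, annotations, name)
  if (length(triples) > 0L) {
    lines <- c(lines,
               '<RDF xmlns="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:myo="https://example.org/cardiac/metadata#">')
    by_subject <- split(triples, vapply(triples, function(t) t$subject, ""))
    for (subj in names(by_subject)) {
      lines <- c(lines, sprintf('  <Description about="#%s">', subj))
      for (tr in by_subject[[subj]]) {
        if (isTRUE(tr$literal)) {
          lines <- c(lines, sprintf("    <myo:%s>%s</myo:%s>",
                                    tr$predicate, tr$object, tr$predicate))
        } else {
          lines <- c(lines,
                     sprintf('    <myo:%s resource="https://example.org/cardiac/metadata#%s"/>',
                             tr$predicate, tr$object))
        }
      }
      lines <- c(lines, "  </Description>")
    }
    lines <- c(lines, "</RDF>")
  }
  lines <- c(lines, "</model>")
  paste(lines, collapse = "\n")
}

annotations_to_triples <- function(flat, annotations, model_name) {
  if (is.null(annotations)) return(list())
  if (!is.null(annotations$triples)) return(annotations$triples)
  triples <- list()
  id_for <- function(var) {
    v <- flat$variables[[var]]
    if (!is.null(v) && length(v$ids) > 0L) v$ids[[1]] else var
  }
  for (var in names(annotations$terms %||% list())) {
    for (term in annotations$terms[[var]]) {
      triples[[length(triples) + 1L]] <-
        list(subject = id_for(var), predicate = "is", object = term)
    }
  }
  for (var in annotations$modifiable %||% character(0)) {
    triples[[length(triples) + 1L]] <-
      list(subject = id_for(var), predicate = "modifiable-parameter",
           object = "yes", literal = TRUE)
  }
  for (var in annotations$derived %||% character(0)) {
    triples[[length(triples) + 1L]] <-
      list(subject = id_for(var), predicate = "derived-quantity",
           object = "yes", literal = TRUE)
  }
  for (var in names(annotations$ranges %||% list())) {
    r <- annotations$ranges[[var]]
    if (is.finite(r[1])) {
      triples[[length(triples) + 1L]] <-
        list(subject = id_for(var), predicate = "range-low",
             object = format(r[1], digits = 17), literal = TRUE)
    }
    if (is.finite(r[2])) {
      triples[[length(triples) + 1L]] <-
        list(subject = id_for(var), predicate = "range-high",
             object = format(r[2], digits = 17), literal = TRUE)
    }
  }
  if (isTRUE(annotations$self_excitatory)) {
    triples[[length(triples) + 1L]] <-
      list(subject = model_name, predicate = "is-self-excitatory",
           object = "yes", literal = TRUE)
  }
  triples
}
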