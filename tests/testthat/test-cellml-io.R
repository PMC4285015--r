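# Document parsing, flattening, annotations, and round-tripping.

test_that("the toy gate document parses with the expected structure", {
  raw <- parse_document(make_toy_gate())
  expect_length(raw$components, 1L)
  comp <- raw$components[[1]]
  expect_length(comp$variables, 14L)
  eqs <- comp$equations
  expect_equal(sum(vapply(eqs, function(e) e$kind == "ode", TRUE)), 2L)
  expect_equal(sum(vapply(eqs, function(e) e$kind == "assign", TRUE)), 4L)
})

test_that("every zoo fixture round-trips through write/parse/flatten", {
  for (nm in fixture_names()) {
    doc <- if (nm == "synthetic_stiff") fixture_document(nm, seed = 3)
           else fixture_document(nm)
    raw <- parse_document(doc)
    flat <- flatten(raw)
    expect_equal(flat$report$status, "ok", info = nm)
    ann <- read_annotations(raw, flat)
    doc2 <- write_document(flat, ann, name = raw$name,
                           unit_definitions = raw$unit_definitions)
    raw2 <- parse_document(doc2)
    flat2 <- flatten(raw2)
    expect_equal(flat2$report$status, "ok", info = nm)
    # structural equality of the flattened equation sets (ordering fixed by
    # the deterministic topological sort)
    eqset <- function(f) {
      c(stats::setNames(lapply(f$assignments, function(a) deparse1(a$rhs)),
                        vapply(f$assignments, function(a) a$var, "")),
        stats::setNames(lapply(f$odes, function(o) deparse1(o$rhs)),
                        paste0("d_", vapply(f$odes, function(o) o$state, ""))))
    }
    e1 <- eqset(flat); e2 <- eqset(flat2)
    expect_setequal(names(e1), names(e2))
    expect_equal(e2[names(e1)], e1, info = nm)
    # annotations preserved
    ann2 <- read_annotations(raw2, flat2)
    expect_equal(ann2$terms[order(names(ann2$terms))],
                 ann$terms[order(names(ann$terms))], info = nm)
    expect_equal(ann2$self_excitatory, ann$self_excitatory)
  }
})

test_that("multi-component models flatten to one canonical symbol per connection", {
  doc <- '<?xml version="1.0"?>
<model name="two_comp" xmlns="http://www.cellml.org/cellml/1.0#">
<units name="mV"><unit units="volt" prefix="milli"/></units>
<units name="ms"><unit units="second" prefix="milli"/></units>
<units name="per_ms"><unit units="second" prefix="milli" exponent="-1"/></units>
<component name="A">
  <variable name="V" units="mV" initial_value="-80" public_interface="out" id="A_V"/>
  <variable name="time" units="ms" public_interface="out"/>
  <math xmlns="http://www.w3.org/1998/Math/MathML">
    <apply><eq/>
      <apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply>
      <apply><times/><cn units="per_ms">-0.1</cn><ci>V</ci></apply>
    </apply>
  </math>
</component>
<component name="B">
  <variable name="V" units="mV" public_interface="in"/>
  <variable name="time" units="ms" public_interface="in"/>
  <variable name="w" units="dimensionless" initial_value="0"/>
  <math xmlns="http://www.w3.org/1998/Math/MathML">
    <apply><eq/>
      <apply><diff/><bvar><ci>time</ci></bvar><ci>w</ci></apply>
      <apply><times/><cn units="per_ms">0.01</cn><ci>V</ci>
        <apply><power/><ci>w</ci><cn units="dimensionless">0</cn></apply></apply>
    </apply>
  </math>
</component>
<connection>
  <map_components component_1="A" component_2="B"/>
  <map_variables variable_1="V" variable_2="V"/>
  <map_variables variable_1="time" variable_2="time"/>
</connection>
</model>'
  flat <- flatten(parse_document(doc))
  expect_equal(flat$report$status, "ok")
  # A.V and B.V merged into one symbol, referenced by both equations
  vnames <- names(flat$variables)
  expect_equal(sum(grepl("V", vnames)), 1L)
  wode <- flat$odes[[which(vapply(flat$odes, function(o) o$state, "") == "w")]]
  expect_true(any(grepl("V", deparse1(wode$rhs))))
})

test_that("deliberately broken fixtures yield exactly their failure category", {
  cases <- list(
    c("missing-parameter", "missing-parameter"),
    c("over-constrained", "over-constrained"),
    c("invalid-units", "invalid-units"),
    c("unsupported-construct", "unsupported-construct"),
    c("cn-no-units", "invalid-units")
  )
  for (cs in cases) {
    res <- convert_cellml(make_broken_fixture(cs[1]))
    expect_equal(res$report$status, "failed", info = cs[1])
    cats <- unique(vapply(res$report$failures, function(f) f$category, ""))
    expect_true(cs[2] %in% cats, info = paste(cs[1], "->", paste(cats, collapse = ",")))
  }
  # the unsupported element is named in the message
  res <- convert_cellml(make_broken_fixture("unsupported-construct"))
  msgs <- vapply(res$report$failures, function(f) f$message, "")
  expect_true(any(grepl("reaction", msgs)))
})

test_that("annotations carry terms, ranges, roles and model-level flags", {
  raw <- parse_document(make_hodgkin_huxley())
  ann <- read_annotations(raw)
  expect_true("membrane_voltage" %in% ann$terms$V)
  expect_true(all(c("stim_amplitude", "stim_duration", "stim_period") %in%
                    names(ann$terms)))
  expect_equal(ann$ranges$m, c(0, 1))
  expect_true("g_Na" %in% ann$modifiable)
  expect_true("i_Na" %in% ann$derived)
  expect_false(ann$self_excitatory)
  ann_se <- read_annotations(parse_document(make_self_excitatory()))
  expect_true(ann_se$self_excitatory)
})

test_that("triples with unknown subjects are ignored with a warning record", {
  doc <- sub("</model>",
             '<RDF xmlns="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:myo="https://example.org/x#">
  <Description about="#no_such_variable">
    <myo:is resource="https://example.org/x#membrane_voltage"/>
  </Description></RDF></model>',
             make_toy_gate(), fixed = TRUE)
  raw <- parse_document(doc)
  ann <- read_annotations(raw)
  expect_true(any(grepl("no_such_variable", ann$warnings)))
  # the bogus triple must not have created a binding
  expect_false("no_such_variable" %in% names(ann$terms))
})

test_that("conversion reports serialize to JSON", {
  res <- convert_cellml(make_broken_fixture("over-constrained"))
  js <- jsonlite::fromJSON(format(res$report))
  expect_equal(js$status, "failed")
  expect_true(nrow(js$failures) >= 1 || length(js$failures) >= 1)
})
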