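# Minimal dimensional analysis for the CellML unit subset.
#
# A unit is (multiplier, dims) where dims is an exponent vector over the SI
# base dimensions (metre, kilogram, second, ampere, mole, kelvin).  Model
# documents may define composite units over these and the predefined derived
# units below, with prefix/exponent/multiplier attributes as in CellML 1.0.

.si_dims <- c("m", "kg", "s", "A", "mol", "K")

unit_new <- function(multiplier = 1, dims = NULL) {
  d <- stats::setNames(numeric(6), .si_dims)
  if (!is.null(dims)) d[names(dims)] <- dims
  structure(list(multiplier = multiplier, dims = d), class = "myo_unit")
}

.si_prefixes <- c(yotta = 24, zetta = 21, exa = 18, peta = 15, tera = 12,
                  giga = 9, mega = 6, kilo = 3, hecto = 2, deka = 1, deca = 1,
                  deci = -1, centi = -2, milli = -3, micro = -6, nano = -9,
                  pico = -12, femto = -15, atto = -18, zepto = -21, yocto = -24)

# Predefined units (CellML built-ins plus the derived units cardiac models use).
base_unit_table <- function() {
  u <- unit_new
  list(
    dimensionless = u(1),
    metre = u(1, c(m = 1)), meter = u(1, c(m = 1)),
    kilogram = u(1, c(kg = 1)), gram = u(1e-3, c(kg = 1)),
    second = u(1, c(s = 1)),
    ampere = u(1, c(A = 1)),
    mole = u(1, c(mol = 1)),
    kelvin = u(1, c(K = 1)),
    litre = u(1e-3, c(m = 3)), liter = u(1e-3, c(m = 3)),
    volt = u(1, c(kg = 1, m = 2, s = -3, A = -1)),
    coulomb = u(1, c(A = 1, s = 1)),
    farad = u(1, c(kg = -1, m = -2, s = 4, A = 2)),
    siemens = u(1, c(kg = -1, m = -2, s = 3, A = 2)),
    ohm = u(1, c(kg = 1, m = 2, s = -3, A = -2)),
    joule = u(1, c(kg = 1, m = 2, s = -2)),
    newton = u(1, c(kg = 1, m = 1, s = -2)),
    watt = u(1, c(kg = 1, m = 2, s = -3)),
    hertz = u(1, c(s = -1)),
    molar = u(1e3, c(mol = 1, m = -3))  # mole per litre
  )
}

unit_mul <- function(a, b) unit_new(a$multiplier * b$multiplier, a$dims + b$dims)
unit_pow <- function(a, p) unit_new(a$multiplier^p, a$dims * p)
unit_scale <- function(a, k) unit_new(a$multiplier * k, a$dims)

unit_same_dim <- function(a, b) all(abs(a$dims - b$dims) < 1e-9)
unit_dimensionless <- function(a) all(abs(a$dims) < 1e-9)

# factor f such that value_in_a * f = value_in_b
unit_conversion_factor <- function(a, b) {
  if (!unit_same_dim(a, b)) {
    stop("units are not dimensionally commensurable", call. = FALSE)
  }
  a$multiplier / b$multiplier
}

# Resolve a unit name against the table of known units.
resolve_unit <- function(name, table) {
  if (!is.null(table[[name]])) return(table[[name]])
  stop("unknown units '", name, "'", call. = FALSE)
}

# Build a composite unit from a list of <unit> attribute sets:
# list(units=, prefix=, exponent=, multiplier=)
compose_unit <- function(parts, table) {
  out <- unit_new(1)
  for (p in parts) {
    u <- resolve_unit(p$units, table)
    ok <- function(x) !is.null(x) && !is.na(x) && nzchar(x)
    pf <- if (ok(p$prefix)) {
      if (grepl("^-?[0-9]+$", p$prefix)) as.numeric(p$prefix)
      else {
        if (!p$prefix %in% names(.si_prefixes)) {
          stop("unknown SI prefix '", p$prefix, "'", call. = FALSE)
        }
        .si_prefixes[[p$prefix]]
      }
    } else 0
    expo <- if (ok(p$exponent)) as.numeric(p$exponent) else 1
    mult <- if (ok(p$multiplier)) as.numeric(p$multiplier) else 1
    u <- unit_scale(u, 10^pf)
    u <- unit_pow(u, expo)
    u <- unit_scale(u, mult)
    out <- unit_mul(out, u)
  }
  out
}

# The standardized convention: target unit per physical category, matched by
# dimension signature (time ms, voltage mV, current density uA/cm^2,
# capacitance density uF/cm^2, concentration mM, conductance density mS/cm^2,
# rates per ms).
standard_conventions <- function() {
  tab <- base_unit_table()
  ms <- unit_scale(tab$second, 1e-3)
  mV <- unit_scale(tab$volt, 1e-3)
  uA_cm2 <- unit_mul(unit_scale(tab$ampere, 1e-6), unit_pow(unit_scale(tab$metre, 1e-2), -2))
  uF_cm2 <- unit_mul(unit_scale(tab$farad, 1e-6), unit_pow(unit_scale(tab$metre, 1e-2), -2))
  uF <- unit_scale(tab$farad, 1e-6)
  uA <- unit_scale(tab$ampere, 1e-6)
  mM <- unit_scale(tab$molar, 1e-3)
  mS_cm2 <- unit_mul(unit_scale(tab$siemens, 1e-3), unit_pow(unit_scale(tab$metre, 1e-2), -2))
  per_ms <- unit_pow(ms, -1)
  mM_per_ms <- unit_mul(mM, per_ms)
  mV_per_ms <- unit_mul(mV, per_ms)
  list(time = ms, voltage = mV, current_density = uA_cm2,
       capacitance_density = uF_cm2, capacitance = uF, current = uA,
       concentration = mM, conductance_density = mS_cm2, rate = per_ms,
       concentration_rate = mM_per_ms, voltage_rate = mV_per_ms)
}

# Find the conventional target for a unit by dimension matching; NULL if the
# unit has no standardized category.
standard_target <- function(u) {
  conv <- standard_conventions()
  for (nm in names(conv)) {
    if (unit_same_dim(u, conv[[nm]])) return(conv[[nm]])
  }
  NULL
}
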