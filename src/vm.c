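/* Stack-machine evaluator for compiled model right-hand sides.
 *
 * The symbolic layer flattens an expression DAG into a linear instruction
 * tape over a register file.  Layout of the ops matrix (integer, n x 5,
 * column-major): opcode, a, b, c, target; a/b/c/target are 0-based register
 * indices except for OP_CONST where `a` indexes the constant pool.
 * Floating overflow follows IEEE rules (Inf/NaN propagate, no errors).
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>
#include <string.h>

enum {
  OP_CONST = 1, OP_ADD, OP_SUB, OP_MUL, OP_DIV, OP_NEG, OP_POW,
  OP_EXP, OP_LOG, OP_LOG10, OP_SQRT, OP_ABS, OP_TANH,
  OP_FLOOR, OP_CEIL, OP_SIGN,
  OP_LT, OP_GT, OP_LE, OP_GE, OP_EQ, OP_NE,
  OP_AND, OP_OR, OP_NOT, OP_SEL
};

SEXP myo_vm_eval(SEXP ops_, SEXP consts_, SEXP inputs_, SEXP nreg_, SEXP outidx_)
{
  const int n = Rf_nrows(ops_);
  const int *op = INTEGER(ops_);
  const int *a = op + n;
  const int *b = op + 2 * n;
  const int *c = op + 3 * n;
  const int *tg = op + 4 * n;
  const double *consts = REAL(consts_);
  const double *inputs = REAL(inputs_);
  const int nin = Rf_length(inputs_);
  const int nreg = INTEGER(nreg_)[0];
  const int *outidx = INTEGER(outidx_);
  const int nout = Rf_length(outidx_);

  double *reg = (double *) R_alloc(nreg, sizeof(double));
  memcpy(reg, inputs, nin * sizeof(double));

  for (int i = 0; i < n; i++) {
    const int t = tg[i];
    switch (op[i]) {
    case OP_CONST: reg[t] = consts[a[i]]; break;
    case OP_ADD: reg[t] = reg[a[i]] + reg[b[i]]; break;
    case OP_SUB: reg[t] = reg[a[i]] - reg[b[i]]; break;
    case OP_MUL: reg[t] = reg[a[i]] * reg[b[i]]; break;
    case OP_DIV: reg[t] = reg[a[i]] / reg[b[i]]; break;
    case OP_NEG: reg[t] = -reg[a[i]]; break;
    case OP_POW: reg[t] = R_pow(reg[a[i]], reg[b[i]]); break;
    case OP_EXP: reg[t] = exp(reg[a[i]]); break;
    case OP_LOG: reg[t] = log(reg[a[i]]); break;
    case OP_LOG10: reg[t] = log10(reg[a[i]]); break;
    case OP_SQRT: reg[t] = sqrt(reg[a[i]]); break;
    case OP_ABS: reg[t] = fabs(reg[a[i]]); break;
    case OP_TANH: reg[t] = tanh(reg[a[i]]); break;
    case OP_FLOOR: reg[t] = floor(reg[a[i]]); break;
    case OP_CEIL: reg[t] = ceil(reg[a[i]]); break;
    case OP_SIGN: reg[t] = (reg[a[i]] > 0) - (reg[a[i]] < 0); break;
    case OP_LT: reg[t] = reg[a[i]] < reg[b[i]]; break;
    case OP_GT: reg[t] = reg[a[i]] > reg[b[i]]; break;
    case OP_LE: reg[t] = reg[a[i]] <= reg[b[i]]; break;
    case OP_GE: reg[t] = reg[a[i]] >= reg[b[i]]; break;
    case OP_EQ: reg[t] = reg[a[i]] == reg[b[i]]; break;
    case OP_NE: reg[t] = reg[a[i]] != reg[b[i]]; break;
    case OP_AND: reg[t] = (reg[a[i]] != 0) && (reg[b[i]] != 0); break;
    case OP_OR: reg[t] = (reg[a[i]] != 0) || (reg[b[i]] != 0); break;
    case OP_NOT: reg[t] = reg[a[i]] == 0; break;
    case OP_SEL: reg[t] = (reg[c[i]] != 0) ? reg[a[i]] : reg[b[i]]; break;
    default: Rf_error("unknown VM opcode %d", op[i]);
    }
  }

  SEXP out = PROTECT(Rf_allocVector(REALSXP, nout));
  double *po = REAL(out);
  for (int k = 0; k < nout; k++) po[k] = reg[outidx[k]];
  UNPROTECT(1);
  return out;
}

/* ------------------------------------------------------------------------
 * Native derivative/Jacobian entry points for deSolve's compiled-model
 * interface: the active tapes are installed from R before each integrator
 * call, then lsoda drives the evaluations without re-entering R.
 */

static SEXP g_rhs_tape = NULL;   /* list(ops, consts, nreg, out_idx) */
static SEXP g_jac_tape = NULL;
static double g_stim[5];         /* amplitude, duration, period, start, end */
static int g_has_stim = 0, g_has_end = 0;
static int g_v_param = 0, g_vi = -1;  /* V-as-parameter mode, 0-based V index */
static double g_vov = 0.0;
static double *g_reg = NULL;
static int g_reg_size = 0;

static void vm_run(SEXP tape, double *reg)
{
  SEXP ops_ = VECTOR_ELT(tape, 0);
  const int n = Rf_nrows(ops_);
  const int *op = INTEGER(ops_);
  const int *a = op + n;
  const int *b = op + 2 * n;
  const int *c = op + 3 * n;
  const int *tg = op + 4 * n;
  const double *consts = REAL(VECTOR_ELT(tape, 1));
  for (int i = 0; i < n; i++) {
    const int t = tg[i];
    switch (op[i]) {
    case OP_CONST: reg[t] = consts[a[i]]; break;
    case OP_ADD: reg[t] = reg[a[i]] + reg[b[i]]; break;
    case OP_SUB: reg[t] = reg[a[i]] - reg[b[i]]; break;
    case OP_MUL: reg[t] = reg[a[i]] * reg[b[i]]; break;
    case OP_DIV: reg[t] = reg[a[i]] / reg[b[i]]; break;
    case OP_NEG: reg[t] = -reg[a[i]]; break;
    case OP_POW: reg[t] = R_pow(reg[a[i]], reg[b[i]]); break;
    case OP_EXP: reg[t] = exp(reg[a[i]]); break;
    case OP_LOG: reg[t] = log(reg[a[i]]); break;
    case OP_LOG10: reg[t] = log10(reg[a[i]]); break;
    case OP_SQRT: reg[t] = sqrt(reg[a[i]]); break;
    case OP_ABS: reg[t] = fabs(reg[a[i]]); break;
    case OP_TANH: reg[t] = tanh(reg[a[i]]); break;
    case OP_FLOOR: reg[t] = floor(reg[a[i]]); break;
    case OP_CEIL: reg[t] = ceil(reg[a[i]]); break;
    case OP_SIGN: reg[t] = (reg[a[i]] > 0) - (reg[a[i]] < 0); break;
    case OP_LT: reg[t] = reg[a[i]] < reg[b[i]]; break;
    case OP_GT: reg[t] = reg[a[i]] > reg[b[i]]; break;
    case OP_LE: reg[t] = reg[a[i]] <= reg[b[i]]; break;
    case OP_GE: reg[t] = reg[a[i]] >= reg[b[i]]; break;
    case OP_EQ: reg[t] = reg[a[i]] == reg[b[i]]; break;
    case OP_NE: reg[t] = reg[a[i]] != reg[b[i]]; break;
    case OP_AND: reg[t] = (reg[a[i]] != 0) && (reg[b[i]] != 0); break;
    case OP_OR: reg[t] = (reg[a[i]] != 0) || (reg[b[i]] != 0); break;
    case OP_NOT: reg[t] = reg[a[i]] == 0; break;
    case OP_SEL: reg[t] = (reg[c[i]] != 0) ? reg[a[i]] : reg[b[i]]; break;
    default: Rf_error("unknown VM opcode %d", op[i]);
    }
  }
}

static double stim_at(double t)
{
  if (!g_has_stim) return 0.0;
  double rel = t - g_stim[3];
  if (rel >= 0 && rel - g_stim[2] * floor(rel / g_stim[2]) < g_stim[1] &&
      (!g_has_end || t <= g_stim[4]))
    return g_stim[0];
  return 0.0;
}

/* install the active model: rhs tape, optional jac tape, stimulus scalars,
 * and V-as-parameter settings */
SEXP myo_vm_set_model(SEXP rhs_tape, SEXP jac_tape, SEXP stim, SEXP vmode)
{
  if (g_rhs_tape) R_ReleaseObject(g_rhs_tape);
  g_rhs_tape = rhs_tape;
  R_PreserveObject(g_rhs_tape);
  if (g_jac_tape) { R_ReleaseObject(g_jac_tape); g_jac_tape = NULL; }
  if (!Rf_isNull(jac_tape)) {
    g_jac_tape = jac_tape;
    R_PreserveObject(g_jac_tape);
  }
  if (Rf_isNull(stim)) {
    g_has_stim = 0;
  } else {
    double *s = REAL(stim);
    g_stim[0] = s[0]; g_stim[1] = s[1]; g_stim[2] = s[2]; g_stim[3] = s[3];
    g_has_end = Rf_length(stim) > 4;
    if (g_has_end) g_stim[4] = s[4];
    g_has_stim = 1;
  }
  if (Rf_isNull(vmode)) {
    g_v_param = 0;
  } else {
    double *v = REAL(vmode);
    g_v_param = 1;
    g_vi = (int) v[0];
    g_vov = v[1];
  }
  int need = INTEGER(VECTOR_ELT(rhs_tape, 2))[0];
  if (g_jac_tape) {
    int nj = INTEGER(VECTOR_ELT(g_jac_tape, 2))[0];
    if (nj > need) need = nj;
  }
  if (need > g_reg_size) {
    g_reg = (double *) R_Realloc(g_reg, need, double);
    g_reg_size = need;
  }
  return R_NilValue;
}

void myo_vm_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
  const int n = *neq;
  double *reg = g_reg;
  memcpy(reg, y, n * sizeof(double));
  if (g_v_param) reg[g_vi] = g_vov;
  reg[n] = *t;
  reg[n + 1] = stim_at(*t);
  vm_run(g_rhs_tape, reg);
  const int *outidx = INTEGER(VECTOR_ELT(g_rhs_tape, 3));
  for (int k = 0; k < n; k++) ydot[k] = reg[outidx[k]];
  if (g_v_param) ydot[g_vi] = 0.0;
}

void myo_vm_jac(int *neq, double *t, double *y, int *ml, int *mu,
                double *pd, int *nrowpd, double *yout, int *ip)
{
  const int n = *neq;
  double *reg = g_reg;
  memcpy(reg, y, n * sizeof(double));
  if (g_v_param) reg[g_vi] = g_vov;
  reg[n] = *t;
  reg[n + 1] = stim_at(*t);
  vm_run(g_jac_tape, reg);
  const int *outidx = INTEGER(VECTOR_ELT(g_jac_tape, 3));
  const int nr = *nrowpd;
  for (int j = 0; j < n; j++)
    for (int i = 0; i < n; i++)
      pd[j * nr + i] = reg[outidx[j * n + i]];
  if (g_v_param)
    for (int j = 0; j < n; j++) pd[j * nr + g_vi] = 0.0;
}
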