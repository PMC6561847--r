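## Boolean network representation, parsing and evaluation.
##
## Rule text format: one "NAME = EXPR" per line (or ';'-separated), '#'
## comments, UTF-8. EXPR uses gene identifiers, literals 0/1, parentheses and
## the operators NOT/AND/OR in any of three spellings: words (NOT, AND, OR,
## case-insensitive), ASCII symbols (!, &, |), or Unicode (¬, ∧, ∨).
## Precedence is NOT > AND > OR. A "FREEZE NAME = 0|1" line pins a gene at a
## constant (mutation overlay).

.normalizeRuleExpr <- function(s) {
  s <- gsub("¬", "!", s)
  s <- gsub("∧", "&", s)
  s <- gsub("∨", "|", s, fixed = TRUE)
  s <- gsub("(?i)\\bNOT\\b", "!", s, perl = TRUE)
  s <- gsub("(?i)\\bAND\\b", "&", s, perl = TRUE)
  s <- gsub("(?i)\\bOR\\b", "|", s, perl = TRUE)
  s
}

# validate an R expression as a pure Boolean formula; returns its variables
.checkRuleExpr <- function(e, gene) {
  if (is.name(e)) return(as.character(e))
  if (is.numeric(e) || is.logical(e)) {
    if (!(as.numeric(e) %in% c(0, 1)))
      stop(sprintf("rule for '%s': literal %s is not 0 or 1", gene, deparse(e)))
    return(character())
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.checkRuleExpr(e[[2]], gene))
    if (op == "!") return(.checkRuleExpr(e[[2]], gene))
    if (op %in% c("&", "|", "&&", "||"))
      return(c(.checkRuleExpr(e[[2]], gene), .checkRuleExpr(e[[3]], gene)))
    stop(sprintf("rule for '%s': operator '%s' is not one of NOT/AND/OR", gene, op))
  }
  stop(sprintf("rule for '%s': cannot interpret '%s'", gene, deparse(e)))
}

#' Parse Boolean network rules
#'
#' Parses rule text (one \code{NAME = EXPR} definition per gene) into a
#' \linkS4class{BooleanNetwork}. Operator spellings NOT/AND/OR, \code{!/&/|}
#' and \verb{¬/∧/∨} are all accepted, with standard Boolean precedence
#' (NOT > AND > OR). \code{FREEZE NAME = 0} lines pin a gene at a constant.
#'
#' @param text a character scalar (lines separated by newlines and/or
#'   semicolons) or a character vector of lines.
#' @return a \linkS4class{BooleanNetwork}.
#' @examples
#' net <- parseRules("A = NOT B\nB = A AND B")
#' evaluateState(net, c(A = 0, B = 1))
#' @export
parseRules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- unlist(strsplit(lines, ";"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no rule definitions found")

  geneNames <- character()
  ruleText <- character()
  exprs <- list()
  frozen <- integer()
  for (ln in lines) {
    frz <- regmatches(ln, regexec("^(?i)FREEZE\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([01])\\s*$",
                                  ln, perl = TRUE))[[1]]
    if (length(frz)) {
      frozen[frz[2]] <- as.integer(frz[3])
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (!length(m)) stop(sprintf("cannot parse rule line: '%s'", ln))
    gene <- m[2]
    if (gene %in% geneNames) stop(sprintf("duplicate definition for gene '%s'", gene))
    rhs <- .normalizeRuleExpr(m[3])
    e <- tryCatch(str2lang(rhs),
                  error = function(err) stop(sprintf("rule for '%s' is not well-formed: %s",
                                                     gene, conditionMessage(err))))
    .checkRuleExpr(e, gene)
    geneNames <- c(geneNames, gene)
    ruleText[gene] <- trimws(m[3])
    exprs[[gene]] <- e
  }
  for (g in geneNames) {
    bad <- setdiff(all.vars(exprs[[g]]), geneNames)
    if (length(bad))
      stop(sprintf("rule for '%s' uses undefined identifier(s): %s",
                   g, paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(frozen), geneNames)
  if (length(bad))
    stop(sprintf("FREEZE for undefined gene(s): %s", paste(bad, collapse = ", ")))
  new("BooleanNetwork", geneNames = geneNames, rules = exprs,
      ruleText = ruleText, frozen = frozen)
}

#' Read Boolean network rules from a file
#'
#' @param path path to a UTF-8 rule file (see \code{\link{parseRules}}).
#' @return a \linkS4class{BooleanNetwork}.
#' @export
readRules <- function(path) {
  parseRules(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Number of genes of a network or model
#' @param object a \linkS4class{BooleanNetwork} or \linkS4class{PobdsModel}.
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname nGenes
#' @export
setMethod("nGenes", "BooleanNetwork", function(object) length(object@geneNames))

#' Gene names
#' @param object a \linkS4class{BooleanNetwork} or \linkS4class{PobdsModel}.
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname geneNames
#' @export
setMethod("geneNames", "BooleanNetwork", function(object) object@geneNames)

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d genes\n", nGenes(object)))
  for (g in object@geneNames) {
    tag <- if (g %in% names(object@frozen))
      sprintf("  [frozen at %d]", object@frozen[[g]]) else ""
    cat(sprintf("  %s = %s%s\n", g, object@ruleText[[g]], tag))
  }
})

#' Freeze genes at constant values
#'
#' Returns a copy of the network in which the named genes ignore their rules
#' and always output the given constants. A frozen gene is stuck: downstream
#' in the POBDS model the Bernoulli perturbation noise is restricted to the
#' free genes, so a stuck-at-OFF gene is always zero, mirroring a mutation
#' that disables a node outright.
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param ... named 0/1 values, e.g. \code{Apoptosis = 0}.
#' @return the modified network.
#' @export
freezeGenes <- function(net, ...) {
  vals <- c(...)
  if (!length(vals)) return(net)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop("freezeGenes() arguments must be named by gene")
  frozen <- net@frozen
  for (g in names(vals)) {
    if (!g %in% net@geneNames) stop(sprintf("unknown gene '%s'", g))
    if (!vals[[g]] %in% c(0, 1)) stop("frozen values must be 0 or 1")
    frozen[g] <- as.integer(vals[[g]])
  }
  initialize(net, frozen = frozen)
}

# postfix compilation of one rule; opcodes match src/pobds_kernels.cpp
.compileExpr <- function(e, geneNames) {
  if (is.name(e)) return(c(1L, match(as.character(e), geneNames)))
  if (is.numeric(e) || is.logical(e)) return(c(2L, as.integer(e)))
  op <- as.character(e[[1]])
  if (op == "(") return(.compileExpr(e[[2]], geneNames))
  if (op == "!") return(c(.compileExpr(e[[2]], geneNames), 3L, 0L))
  if (op %in% c("&", "&&"))
    return(c(.compileExpr(e[[2]], geneNames), .compileExpr(e[[3]], geneNames), 4L, 0L))
  if (op %in% c("|", "||"))
    return(c(.compileExpr(e[[2]], geneNames), .compileExpr(e[[3]], geneNames), 5L, 0L))
  stop(sprintf("cannot compile operator '%s'", op))
}

# compile a network to the integer-program form consumed by the C++ kernels
.compileNetwork <- function(net) {
  gn <- net@geneNames
  list(prog = lapply(net@rules, .compileExpr, geneNames = gn),
       frozenIdx = match(names(net@frozen), gn),
       frozenVal = unname(net@frozen))
}

# reference evaluator: plain R eval of the rule expressions (used as the
# independent cross-check of the compiled path in the tests)
.evalStatesR <- function(net, states) {
  states <- .asStateMatrix(states, nGenes(net))
  env <- as.list(as.data.frame(states * 1))
  names(env) <- net@geneNames
  out <- vapply(net@geneNames, function(g) {
    v <- eval(net@rules[[g]], envir = env)
    as.integer(rep_len(v, nrow(states)) != 0)
  }, integer(nrow(states)))
  out <- matrix(as.integer(out), nrow = nrow(states),
                dimnames = list(NULL, net@geneNames))
  for (g in names(net@frozen)) out[, g] <- net@frozen[[g]]
  out
}

.asStateMatrix <- function(x, n) {
  if (is.null(dim(x))) {
    if (length(x) != n)
      stop(sprintf("state has %d bits, network has %d genes", length(x), n))
    x <- matrix(as.integer(x), nrow = 1)
  } else {
    if (ncol(x) != n)
      stop(sprintf("state matrix has %d columns, network has %d genes", ncol(x), n))
    x <- matrix(as.integer(x), nrow = nrow(x))
  }
  if (anyNA(x) || !all(x %in% c(0L, 1L))) stop("states must be 0/1")
  x
}

#' Evaluate the network function
#'
#' Computes the deterministic (noise-free) one-step update f(x), with frozen
#' genes forced to their constants.
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param x a 0/1 vector of length n, or an m x n matrix of states (one per
#'   row).
#' @return the updated state(s), same shape as \code{x}, gene-named.
#' @export
evaluateState <- function(net, x) {
  vec <- is.null(dim(x))
  xm <- .asStateMatrix(x, nGenes(net))
  cmp <- .compileNetwork(net)
  out <- cpp_eval_states(xm, cmp$prog, cmp$frozenIdx, cmp$frozenVal)
  colnames(out) <- net@geneNames
  if (vec) setNames(out[1L, ], net@geneNames) else out
}

#' Canonical state encoding
#'
#' Gene j (1-based, in rule-file order) contributes bit value
#' \code{x[j] * 2^(j-1)}; indices are 1-based, so
#' \code{index = 1 + sum_j x[j] * 2^(j-1)}.
#'
#' @param x a 0/1 state vector or an m x n matrix of states.
#' @return integer index/indices in 1..2^n.
#' @export
stateToIndex <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1)
  n <- ncol(x)
  if (n > 30) stop("index encoding supports up to 30 genes")
  as.integer(1 + x %*% 2^(seq_len(n) - 1))
}

#' @rdname stateToIndex
#' @param i integer index/indices in 1..2^n.
#' @param n number of genes.
#' @return for \code{indexToState}: an m x n 0/1 matrix (one row per index).
#' @export
indexToState <- function(i, n) {
  i <- as.integer(i) - 1L
  if (any(i < 0L | i >= 2^n)) stop("index out of range")
  m <- vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(i, j - 1L), 1L),
              integer(length(i)))
  matrix(as.integer(m), nrow = length(i))
}

#' All 2^n states in canonical order
#' @param n number of genes (n <= guard; see options(scPOBDS.matrixGuard=)).
#' @return a 2^n x n 0/1 matrix whose row i is the state with index i.
#' @export
stateMatrix <- function(n) {
  checkMatrixGuard(n, "state enumeration")
  indexToState(seq_len(2^n), n)
}

#' Iterate the noise-free network to its attractor
#'
#' Repeatedly applies \code{evaluateState} from a start state until a state
#' repeats, returning the transient length and the attractor cycle. The state
#' space is finite, so this always terminates within 2^n steps.
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param x0 start state (0/1 vector).
#' @param maxSteps safety cap on iterations.
#' @return list with \code{transient} (steps before entering the cycle),
#'   \code{period} (cycle length) and \code{cycle} (matrix of cycle states).
#' @export
reachAttractor <- function(net, x0, maxSteps = 2^nGenes(net) + 1) {
  x <- as.integer(x0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- list()
  for (k in seq_len(maxSteps + 1)) {
    key <- paste(x, collapse = "")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      period <- k - hit
      cyc <- do.call(rbind, path[hit:(k - 1)])
      colnames(cyc) <- net@geneNames
      return(list(transient = hit - 1L, period = period, cycle = cyc))
    }
    seen[[key]] <- k
    path[[k]] <- x
    x <- unname(evaluateState(net, x))
  }
  stop("no cycle found within maxSteps (should not happen for maxSteps >= 2^n)")
}
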