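# Shared fixtures and independent oracles, built in code at test time.

# Three-reaction chain: EX_in -> A, r_ab: A -> B, EX_out: B ->
chain_model <- function(bound = 10, gpr_ab = "gA") {
  metabolic_model(
    data.frame(id = c("A", "B")),
    list(reaction("EX_in", c(A = 1), 0, bound),
         reaction("r_ab", c(A = -1, B = 1), 0, bound, gpr = gpr_ab),
         reaction("EX_out", c(B = -1), 0, bound)))
}

# Independent shunting-yard parser used as an oracle for parse_gpr:
# classic operator-stack algorithm, structurally unrelated to the
# recursive-descent implementation.
gpr_oracle_parse <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z0-9_.-]+|\\(|\\)", text))[[1]]
  prec <- c(and = 2, or = 1)
  out <- list()
  ops <- character(0)
  reduce <- function() {
    op <- ops[length(ops)]
    ops <<- ops[-length(ops)]
    rhs <- out[[length(out)]]
    lhs <- out[[length(out) - 1L]]
    out[[length(out) - 1L]] <<- list(op = op, args = list(lhs, rhs))
    out[[length(out)]] <<- NULL
  }
  for (tk in toks) {
    lt <- tolower(tk)
    if (lt %in% c("and", "or")) {
      while (length(ops) && ops[length(ops)] %in% c("and", "or") &&
             prec[[ops[length(ops)]]] >= prec[[lt]]) reduce()
      ops <- c(ops, lt)
    } else if (tk == "(") {
      ops <- c(ops, "(")
    } else if (tk == ")") {
      while (ops[length(ops)] != "(") reduce()
      ops <- ops[-length(ops)]
    } else {
      out[[length(out) + 1L]] <- list(gene = tk)
    }
  }
  while (length(ops)) reduce()
  out[[1L]]
}

gpr_oracle_eval <- function(tree, values) {
  if (!is.null(tree$gene)) return(values[[tree$gene]])
  child <- vapply(tree$args, gpr_oracle_eval, numeric(1), values = values)
  if (tree$op == "or") max(child) else min(child)
}

# Random infix rule over the given genes (always syntactically valid)
random_gpr_text <- function(genes, depth = 2) {
  if (depth == 0 || runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  lhs <- random_gpr_text(genes, depth - 1)
  rhs <- random_gpr_text(genes, depth - 1)
  if (runif(1) < 0.5) paste0("(", lhs, " ", op, " ", rhs, ")")
  else paste(lhs, op, rhs)
}

# Small random iMAT instance: toy network plus random high/low sets
random_imat_instance <- function(seed, max_states = 8) {
  net <- make_toy_network(n_reactions = sample(3:7, 1),
                          n_branches = sample(0:2, 1),
                          and_fraction = 0.3,
                          reversible_fraction = 0.3,
                          seed = seed)
  model <- apply_media_constraints(net$model, default_media_constraints())
  rids <- reaction_ids(model)
  n_states <- sample(2:max_states, 1)
  picked <- sample(rids, min(n_states, length(rids)))
  n_high <- sample(0:length(picked), 1)
  list(model = model,
       states = list(high = picked[seq_len(n_high)],
                     low = setdiff(picked, picked[seq_len(n_high)])))
}

# Exhaustive two-sided Fisher p oracle: hypergeometric probabilities from
# first principles (choose()), probability-mass rule.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# Expression matrix with planted shifts, built directly (independent of
# the package's network-tied generator)
planted_expression <- function(n_genes = 60, n_planted = 10, n_per_group = 20,
                               shift = 1, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(2 * n_per_group))
  group <- rep(c("CN", "AD"), each = n_per_group)
  vals <- matrix(rnorm(n_genes * length(samples), 7, noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  planted <- genes[seq_len(n_planted)]
  vals[planted, group == "AD"] <- vals[planted, group == "AD"] + shift
  md <- data.frame(sample = samples, group = group,
                   sex = rep(c("F", "M"), length.out = length(samples)),
                   age = seq(70, 95, length.out = length(samples)),
                   batch = rep(c("b1", "b1", "b2", "b2"),
                               length.out = length(samples)))
  list(expr = expression_matrix(vals, md), planted = planted)
}
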