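# Synthetic chemical spaces with planted reaction rules. These generate all
# data needed to exercise the system: no external dataset is required.

#' A planted reaction rule
#'
#' A rule fires for an experiment when the experiment's compound multiset
#' contains the rule's compounds (rules are subset-closed: a mixture
#' containing a reactive pair is itself reactive through that pair).
#'
#' @param compounds Character vector of 2-4 compound ids (duplicated id =
#'   self-reaction).
#' @param bits Outcome bit positions the rule sets (default 1).
#' @param width Outcome width the bits refer to.
#' @return A `planted_rule` object.
#' @export
planted_rule <- function(compounds, bits = 1L, width = 1L) {
  stopifnot(length(compounds) %in% 2:4, all(bits >= 1L), all(bits <= width))
  structure(list(compounds = sort_c(as.character(compounds)),
                 bits = as.integer(bits), width = as.integer(width)),
            class = "planted_rule")
}

multiset_contains <- function(ids, needed) {
  tn <- table(needed)
  ti <- table(ids)
  all(names(tn) %in% names(ti)) && all(ti[names(tn)] >= tn)
}

#' Deterministic outcome source from planted rules
#'
#' @param rules List of [planted_rule()]s sharing one width.
#' @param width Outcome width.
#' @return A function mapping an id vector to its 0/1 outcome vector: the
#'   union of the bits of every rule whose compounds are contained in the
#'   experiment.
#' @export
outcome_from_rules <- function(rules, width = 1L) {
  force(rules); force(width)
  function(ids) {
    v <- integer(width)
    for (r in rules) {
      if (multiset_contains(ids, r$compounds)) v[r$bits] <- 1L
    }
    v
  }
}

#' Diels-Alder toy chemical space
#'
#' Six compounds: an acid, a base, two inert fillers, a dienophile-only
#' partner and cyclopentadiene (self-reactive). Planted binary rules:
#' acid + base, cyclopentadiene + itself, cyclopentadiene + dienophile;
#' everything else is unreactive. The space is constructed so that the
#' minimal explanation requires four abstract properties in total, two of
#' them carried by cyclopentadiene (its diene and dienophile characters).
#'
#' @param unobserved Character vector of experiment keys to drop from the
#'   observed experiment list (unexplored combinations).
#' @return List with `space`, `outcome_source`, `rules`, `experiments`
#'   (the observed pairs, including the cyclopentadiene self-pair) and
#'   `expected` (`total_properties = 4`,
#'   `cyclopentadiene_properties = 2`).
#' @export
make_diels_alder_space <- function(unobserved = character(0)) {
  comps <- list(
    compound("acid", "acetic acid", "CC(=O)O"),
    compound("base", "triethylamine", "CCN(CC)CC"),
    compound("filler1", "hexane", "CCCCCC"),
    compound("filler2", "toluene", "Cc1ccccc1"),
    compound("dienophile", "maleic anhydride", "O=C1OC(=O)C=C1"),
    compound("cpd", "cyclopentadiene", "C1C=CC=C1", self_reactive = TRUE)
  )
  space <- chemical_space(comps, arities = 2L)
  rules <- list(planted_rule(c("acid", "base")),
                planted_rule(c("cpd", "cpd")),
                planted_rule(c("cpd", "dienophile")))
  exps <- enumerate_experiments(space, include_self = TRUE)
  keys <- vapply(exps, experiment_key, character(1))
  exps <- exps[!keys %in% unobserved]
  list(space = space,
       outcome_source = outcome_from_rules(rules),
       rules = rules,
       experiments = exps,
       expected = list(total_properties = 4L,
                       cyclopentadiene_properties = 2L))
}

#' Passerini 9-compound chemical space
#'
#' Nine compounds with SMILES: one isocyanide, two carboxylic acids, two
#' carbonyl compounds, two amines and two inert solvents. Planted rules:
#' any acid + amine pair is reactive (acid-base mode), and the ternary
#' acid + carbonyl + isocyanide combination is reactive (the Passerini
#' three-component mode). Rules are subset-closed, so a ternary mixture
#' containing an acid-amine pair is also reactive. Enumeration yields
#' 36 binary and 84 ternary experiments.
#'
#' @return List with `space`, `outcome_source` (works for both arities),
#'   `rules` and `classes` (ids grouped by functional class).
#' @export
make_passerini_space <- function() {
  comps <- list(
    compound("iso", "tert-butyl isocyanide", "CC(C)(C)[N+]#[C-]"),
    compound("acid1", "acetic acid", "CC(=O)O"),
    compound("acid2", "benzoic acid", "OC(=O)c1ccccc1"),
    compound("carb1", "benzaldehyde", "O=Cc1ccccc1"),
    compound("carb2", "acetone", "CC(C)=O"),
    compound("amine1", "butylamine", "CCCCN"),
    compound("amine2", "aniline", "Nc1ccccc1"),
    compound("inert1", "hexane", "CCCCCC"),
    compound("inert2", "toluene", "Cc1ccccc1")
  )
  space <- chemical_space(comps, arities = 2:3)
  classes <- list(isocyanide = "iso", acid = c("acid1", "acid2"),
                  carbonyl = c("carb1", "carb2"),
                  amine = c("amine1", "amine2"),
                  inert = c("inert1", "inert2"))
  rules <- list()
  for (a in classes$acid) for (am in classes$amine) {
    rules[[length(rules) + 1L]] <- planted_rule(c(a, am))
  }
  for (a in classes$acid) for (cb in classes$carbonyl) {
    rules[[length(rules) + 1L]] <- planted_rule(c(a, cb, "iso"))
  }
  list(space = space, outcome_source = outcome_from_rules(rules),
       rules = rules, classes = classes)
}

# The named-reaction panel: reagent sets and detected 8-bit reactivity
# vectors; bold positions mark reactivity unique to the full reagent set
# (not observed for any sub-combination).
named_reaction_table <- function() {
  list(
    aldol = list(reagents = c("11", "13", "19"),
                 vector = "00000001", bold = 8L),
    buchwald_hartwig = list(reagents = c("11", "12", "18", "19"),
                            vector = "00000100", bold = 6L),
    heck = list(reagents = c("10", "11", "18", "19"),
                vector = "00000100", bold = 6L),
    mannich = list(reagents = c("11", "12", "13", "20"),
                   vector = "01000001", bold = 8L),
    sonogashira = list(reagents = c("11", "14", "18", "19"),
                       vector = "00001100", bold = 6L),
    suzuki = list(reagents = c("11", "17", "18", "19"),
                  vector = "00000110", bold = 6L),
    wittig = list(reagents = c("13", "16", "19"),
                  vector = "00000111", bold = 7L),
    wittig_horner = list(reagents = c("13", "15", "19"),
                         vector = "00000010", bold = 7L)
  )
}

# Attribute each non-bold bit of each reaction to its largest proper reagent
# subsets that are consistent with every tabulated row: a subset A may emit
# bit b only if every reaction whose reagent set contains A shows b as a
# non-bold bit (bold bits are by definition absent for sub-combinations).
attribute_subset_bits <- function(table) {
  attributions <- list()
  for (nm in names(table)) {
    row <- table[[nm]]
    bits <- which(string_to_bits(row$vector) == 1L)
    nonbold <- setdiff(bits, row$bold)
    if (length(nonbold) == 0L) next
    subs <- combn(row$reagents, length(row$reagents) - 1L, simplify = FALSE)
    for (b in nonbold) {
      for (A in subs) {
        safe <- TRUE
        for (other in table) {
          if (all(A %in% other$reagents)) {
            obits <- which(string_to_bits(other$vector) == 1L)
            if (!(b %in% setdiff(obits, other$bold))) { safe <- FALSE; break }
          }
        }
        if (safe) {
          attributions[[length(attributions) + 1L]] <-
            list(subset = A, bit = b)
        }
      }
    }
  }
  attributions
}

#' Named-reaction chemical space with 8-bit reactivity vectors
#'
#' Eleven compounds labelled `"10"`-`"20"` participating in a panel of
#' landmark named reactions (aldol condensation, Buchwald-Hartwig
#' amination, Heck, Mannich, Sonogashira, Suzuki, Wittig and Wittig-Horner
#' reactions). The outcome source returns each reaction's detected 8-bit
#' reactivity vector for its full reagent set; bits not unique to a
#' reaction are also emitted by the largest proper reagent subsets
#' consistent with the whole panel; all other combinations give the
#' all-zero vector. Full enumeration over arities 2-4 has 550 experiments.
#' Compound structures are representative synthetic stand-ins.
#'
#' @return List with `space`, `outcome_source` (id vector -> 8-bit vector),
#'   `table` (the reaction panel), `reactions` (reagent-set keys by name)
#'   and `width = 8`.
#' @export
make_named_reaction_space <- function() {
  comps <- list(
    compound("10", "styrene", "C=Cc1ccccc1"),
    compound("11", "4'-iodoacetophenone", "CC(=O)c1ccc(I)cc1"),
    compound("12", "aniline", "Nc1ccccc1"),
    compound("13", "benzaldehyde", "O=Cc1ccccc1"),
    compound("14", "phenylacetylene", "C#Cc1ccccc1"),
    compound("15", "diethyl benzylphosphonate", "CCOP(=O)(OCC)Cc1ccccc1"),
    compound("16", "benzyltriphenylphosphonium ylide",
             "C(c1ccccc1)=P(c1ccccc1)(c1ccccc1)c1ccccc1"),
    compound("17", "phenylboronic acid", "OB(O)c1ccccc1"),
    compound("18", "palladium acetate catalyst", NULL),
    compound("19", "DBU (base)", "C1CCC2=NCCCN2CC1"),
    compound("20", "dimethylamine", "CNC")
  )
  space <- chemical_space(comps, arities = 2:4)
  table <- named_reaction_table()
  attributions <- attribute_subset_bits(table)
  outcome_source <- function(ids) {
    v <- integer(8L)
    for (row in table) {
      if (all(row$reagents %in% ids)) {
        v[string_to_bits(row$vector) == 1L] <- 1L
      }
    }
    for (at in attributions) {
      if (all(at$subset %in% ids)) v[at$bit] <- 1L
    }
    v
  }
  reactions <- lapply(table, function(r) experiment_key(r$reagents))
  list(space = space, outcome_source = outcome_source, table = table,
       attributions = attributions, reactions = reactions, width = 8L)
}

#' Simulate an observation log from an outcome source
#'
#' Enumerates the space (or takes an explicit experiment list), queries the
#' outcome source, applies independent bit-flip noise (`eps_fp` on 0-bits,
#' `eps_fn` on 1-bits) and assigns exploration order.
#'
#' @param space A [chemical_space()].
#' @param outcome_source Function id vector -> 0/1 outcome vector.
#' @param order `"canonical"` or `"shuffled"`.
#' @param noise A [noise_model()], or a plain list with `eps_fp`/`eps_fn`
#'   rates in `[0, 1]` (the generator, unlike the inference channel, may
#'   flip at arbitrary rates). Default is noise-free.
#' @param seed Optional seed controlling shuffling and bit flips.
#' @param experiments Optional explicit experiment list (overrides
#'   enumeration).
#' @param include_self Passed to [enumerate_experiments()].
#' @return An [observation_log()].
#' @export
simulate_log <- function(space, outcome_source,
                         order = c("canonical", "shuffled"),
                         noise = list(eps_fp = 0, eps_fn = 0), seed = NULL,
                         experiments = NULL, include_self = FALSE) {
  stopifnot(noise$eps_fp >= 0, noise$eps_fp <= 1,
            noise$eps_fn >= 0, noise$eps_fn <= 1)
  order <- match.arg(order)
  if (is.null(experiments)) {
    experiments <- enumerate_experiments(space, include_self = include_self)
  }
  if (!is.null(seed)) set.seed(seed)
  if (order == "shuffled") {
    experiments <- experiments[sample.int(length(experiments))]
  }
  outs <- do.call(rbind, lapply(experiments,
                                function(e) as.integer(outcome_source(e))))
  if (noise$eps_fp > 0 || noise$eps_fn > 0) {
    flip <- matrix(runif(length(outs)), nrow(outs))
    prob <- ifelse(outs == 1L, noise$eps_fn, noise$eps_fp)
    outs <- ifelse(flip < prob, 1L - outs, outs)
    storage.mode(outs) <- "integer"
  }
  observation_log(experiments, outs)
}
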