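#' Default target reaction groups and their concept specifications
#'
#' Eight cutaneous reaction groups: rash, acne, pruritus, nail changes,
#' xerosis (dry skin), hypohidrosis, bullous eruption and psoriasis. Each
#' group carries a seed concept (CUI-style id), synonyms, optional direct
#' is-a children (only "nail changes" is expanded through the hierarchy),
#' colloquial patient phrasings, and the canonical surface phrases the
#' corpus generator embeds in posts.
#'
#' @return A named list of group specifications.
#' @export
default_group_specs <- function() {
  list(
    rash = list(
      group_id = "rash", seed_concept_id = "C0015230", seed_name = "Rash",
      synonyms = c("Skin rash", "Exanthema"), expand_children = FALSE,
      children = NULL,
      colloquial = c("broke out in red bumps", "skin eruption all over"),
      phrases = c("rash", "skin rash")
    ),
    acne = list(
      group_id = "acne", seed_concept_id = "C0001144", seed_name = "Acne",
      synonyms = c("Acne vulgaris", "Pimples"), expand_children = FALSE,
      children = NULL,
      colloquial = c("breaking out in pimples"),
      phrases = c("acne", "pimples")
    ),
    pruritus = list(
      group_id = "pruritus", seed_concept_id = "C0033774",
      seed_name = "Pruritus",
      synonyms = c("Itching", "Itchy skin"), expand_children = FALSE,
      children = NULL,
      colloquial = c("itching like crazy"),
      phrases = c("itching", "itchy skin")
    ),
    `nail changes` = list(
      group_id = "nail changes", seed_concept_id = "C0027339",
      seed_name = "Disorder of nail",
      synonyms = c("Nail disorder"), expand_children = TRUE,
      children = list(
        list(concept_id = "C0027343", name = "Ingrown toenail",
             synonyms = "Ingrowing nail"),
        list(concept_id = "C0263531", name = "Peeling of nails",
             synonyms = "Nail peeling"),
        list(concept_id = "C0221260", name = "Brittle nails",
             synonyms = character())
      ),
      colloquial = c("my nails are lifting"),
      phrases = c("nail peeling", "brittle nails", "ingrown toenail")
    ),
    xerosis = list(
      group_id = "xerosis", seed_concept_id = "C0151908",
      seed_name = "Dry skin",
      synonyms = c("Xerosis"), expand_children = FALSE, children = NULL,
      colloquial = c("skin so dry it cracks"),
      phrases = c("dry skin", "xerosis")
    ),
    hypohidrosis = list(
      group_id = "hypohidrosis", seed_concept_id = "C0020620",
      seed_name = "Hypohidrosis",
      synonyms = c("Decreased sweating", "Inability to sweat"),
      expand_children = FALSE, children = NULL,
      colloquial = c("stopped sweating completely"),
      phrases = c("hypohidrosis", "decreased sweating")
    ),
    `bullous eruption` = list(
      group_id = "bullous eruption", seed_concept_id = "C0005758",
      seed_name = "Bullous eruption",
      synonyms = c("Blistering eruption", "Blisters"),
      expand_children = FALSE, children = NULL,
      colloquial = c("skin blistering badly"),
      phrases = c("blisters", "blistering eruption")
    ),
    psoriasis = list(
      group_id = "psoriasis", seed_concept_id = "C0033860",
      seed_name = "Psoriasis",
      synonyms = c("Psoriasis flare"), expand_children = FALSE,
      children = NULL,
      colloquial = c("psoriasis flaring up"),
      phrases = c("psoriasis", "psoriasis flare")
    )
  )
}

#' Default target group ids (length 8)
#' @return Character vector of the eight reaction group ids.
#' @export
default_target_groups <- function() {
  names(default_group_specs())
}

#' Default comparison drug list (27 highly discussed drugs)
#'
#' Stand-in for a frequency-ranked comparison list from a real forum; used to
#' enumerate negative-control candidate pairs.
#'
#' @return Character vector of 27 drug ids.
#' @export
default_comparison_drugs <- function() {
  c("metformin", "zoledronic acid", "capecitabine", "lisinopril",
    "atorvastatin", "levothyroxine", "omeprazole", "metoprolol",
    "amlodipine", "simvastatin", "losartan", "gabapentin", "sertraline",
    "furosemide", "warfarin", "tamoxifen", "anastrozole", "letrozole",
    "trastuzumab", "bevacizumab", "carboplatin", "paclitaxel", "docetaxel",
    "gemcitabine", "pemetrexed", "rituximab", "cyclophosphamide")
}

#' Generative configuration for a synthetic forum corpus
#'
#' Specifies a multi-user forum corpus with planted drug–reaction association
#' strengths. Per post, each drug is mentioned independently with its
#' `mention_prob`; conditional on a mentioned drug, each reaction group is
#' emitted with the pair's emission probability (the `background_emission`
#' unless overridden by a `planted` pair). A post mentioning several drugs
#' attributes every emitted reaction to each mentioned drug.
#'
#' @param n_users Number of forum users (default 5000).
#' @param posts_per_user_mean Poisson mean of posts per user (default 3).
#' @param drugs Tibble `drug_id`, `role` (`"target"`/`"comparison"`),
#'   `mention_prob`, optional `brand` (brand-name alias or `NA`).
#' @param groups Group specifications (default [default_group_specs()]).
#' @param background_emission Per-post P(report group | drug mentioned) for
#'   unplanted pairs (default 0.01).
#' @param planted Optional tibble `drug_id`, `group_id`, `emission_prob`
#'   overriding the background for specific pairs.
#' @param colloquial_rate Probability that a generated reaction phrase uses a
#'   colloquial variant rather than a canonical name (default 0.3).
#' @param brand_rate Probability that a drug mention uses the brand alias
#'   when one exists (default 0.3).
#' @param indication_rate Per-post probability of an indication mention
#'   (default 0.1).
#' @param date_range Length-2 date range posts are drawn from (default
#'   2005-01-01 to 2016-12-31).
#' @param seed Integer seed.
#' @return A `gen_config` object.
#' @export
gen_config <- function(n_users = 5000L,
                       posts_per_user_mean = 3,
                       drugs = NULL,
                       groups = default_group_specs(),
                       background_emission = 0.01,
                       planted = NULL,
                       colloquial_rate = 0.3,
                       brand_rate = 0.3,
                       indication_rate = 0.1,
                       date_range = c("2005-01-01", "2016-12-31"),
                       seed = 1L) {
  if (is.null(drugs)) {
    drugs <- tibble::tibble(
      drug_id = c("erlotinib", default_comparison_drugs()[1:9]),
      role = c("target", rep("comparison", 9)),
      mention_prob = 0.03,
      brand = c("Tarceva", rep(NA_character_, 9))
    )
  }
  if (!"brand" %in% names(drugs)) drugs$brand <- NA_character_
  stopifnot(nrow(drugs) >= 1, length(groups) >= 1,
            all(drugs$role %in% c("target", "comparison")))
  check_prob(drugs$mention_prob, "mention_prob")
  check_prob(background_emission, "background_emission")
  check_prob(colloquial_rate, "colloquial_rate")
  check_prob(brand_rate, "brand_rate")
  check_prob(indication_rate, "indication_rate")
  if (!is.null(planted)) {
    check_prob(planted$emission_prob, "planted$emission_prob")
    stopifnot(all(planted$drug_id %in% drugs$drug_id),
              all(planted$group_id %in% names(groups)))
  }
  if (posts_per_user_mean <= 0) {
    stop_adr("`posts_per_user_mean` must be positive.", "adrsignal_bad_argument")
  }
  structure(
    list(n_users = as.integer(n_users),
         posts_per_user_mean = posts_per_user_mean,
         drugs = drugs, groups = groups,
         background_emission = background_emission,
         planted = planted,
         colloquial_rate = colloquial_rate, brand_rate = brand_rate,
         indication_rate = indication_rate,
         date_range = as.Date(date_range), seed = as.integer(seed)),
    class = "gen_config"
  )
}

#' @export
print.gen_config <- function(x, ...) {
  cat("<gen_config> ", x$n_users, " users, ", nrow(x$drugs), " drugs, ",
      length(x$groups), " groups, background emission ",
      x$background_emission, ", ",
      if (is.null(x$planted)) 0 else nrow(x$planted),
      " planted pair(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Internal: drugs x groups emission-probability matrix.
emission_matrix <- function(config) {
  D <- nrow(config$drugs); G <- length(config$groups)
  P <- matrix(config$background_emission, D, G,
              dimnames = list(config$drugs$drug_id, names(config$groups)))
  if (!is.null(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      P[config$planted$drug_id[i], config$planted$group_id[i]] <-
        config$planted$emission_prob[i]
    }
  }
  P
}

DRUG_TEMPLATES <- c("i started %s last month and feel hopeful.",
                    "my doctor put me on %s after the scan.",
                    "been taking %s for six weeks now.")
ADR_TEMPLATES <- c("i have been dealing with %s since then.",
                   "the %s is getting worse every day.",
                   "anyone else get %s on this treatment?")
IND_TEMPLATES <- c("i was diagnosed with %s last spring.",
                   "my %s was found during a routine visit.")
IND_PHRASES <- c("lung cancer", "melanoma", "breast cancer", "kidney disease")
FILLER_SENTENCES <- c(
  "hope everyone is doing well this week.",
  "thanks for all the kind replies.",
  "we are staying positive and taking it one day at a time.",
  "sending good thoughts to everyone here.",
  "the weather has finally improved around here."
)

template_prefix <- function(templates) {
  nchar(sub("%s.*$", "", templates))
}

#' Generate a synthetic forum corpus with gold annotations
#'
#' Samples, per user, a Poisson post count; per post, independent drug
#' mentions and conditional reaction emissions per the configuration; and
#' renders each post as templated sentences (drug mention, reaction phrase —
#' canonical or colloquial —, occasional indication mention, neutral filler)
#' in shuffled order. Gold entity spans are emitted at the exact character
#' offsets of the inserted phrases, and the gold pair table lists every
#' (mentioned drug, emitted group) per post. Byte-identical for a fixed seed.
#'
#' @param config A [gen_config()].
#' @return A `gold_bundle`: list with `posts` (post tibble), `spans` (gold
#'   standoff spans with `label` ADR/IND), `pairs` (gold pair records),
#'   `aliases` (drug alias table), `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(config$seed)
  drugs <- config$drugs
  group_ids <- names(config$groups)
  D <- nrow(drugs); G <- length(group_ids)
  EM <- emission_matrix(config)

  n_posts_user <- stats::rpois(config$n_users, config$posts_per_user_mean)
  P <- sum(n_posts_user)
  if (P == 0) {
    stop_adr("Configuration generated zero posts; increase n_users or the post rate.",
             "adrsignal_empty_corpus")
  }
  user_of_post <- rep(sprintf("u%05d", seq_len(config$n_users)), n_posts_user)
  post_id <- sprintf("p%07d", seq_len(P))
  days <- as.integer(config$date_range[2] - config$date_range[1])
  created_at <- config$date_range[1] + sample.int(days + 1L, P, replace = TRUE) - 1L

  # drug mentions: P x D
  M <- matrix(stats::runif(P * D), P, D) < rep(drugs$mention_prob, each = P)
  # reaction presence: emitted by >= 1 mentioned drug
  presence <- matrix(FALSE, P, G)
  for (j in seq_len(D)) {
    for (g in seq_len(G)) {
      presence[, g] <- presence[, g] |
        (M[, j] & (stats::runif(P) < EM[j, g]))
    }
  }

  # gold pair records: (drug mentioned, group present) per post
  pair_list <- list()
  for (j in seq_len(D)) {
    for (g in seq_len(G)) {
      idx <- which(M[, j] & presence[, g])
      if (length(idx) > 0) {
        pair_list[[length(pair_list) + 1L]] <- tibble::tibble(
          drug_id = drugs$drug_id[j], group_id = group_ids[g],
          user_id = user_of_post[idx], post_id = post_id[idx],
          date = created_at[idx]
        )
      }
    }
  }
  pairs <- dplyr::bind_rows(pair_list)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(drug_id = character(), group_id = character(),
                            user_id = character(), post_id = character(),
                            date = as.Date(character()))
  }
  pairs <- dplyr::arrange(pairs, .data$post_id, .data$drug_id, .data$group_id)

  # --- sentence rows -------------------------------------------------------
  rows <- list()
  # drug-mention sentences
  dm <- which(M, arr.ind = TRUE)
  if (nrow(dm) > 0) {
    j <- dm[, 2]
    has_brand <- !is.na(drugs$brand[j])
    use_brand <- has_brand & (stats::runif(nrow(dm)) < config$brand_rate)
    alias <- ifelse(use_brand, drugs$brand[j], drugs$drug_id[j])
    tmpl <- sample.int(length(DRUG_TEMPLATES), nrow(dm), replace = TRUE)
    rows$drug <- tibble::tibble(
      post = dm[, 1],
      text = sprintf(DRUG_TEMPLATES[tmpl], alias),
      phrase = NA_character_, prefix = NA_integer_, label = NA_character_
    )
  }
  # reaction sentences, one per present (post, group)
  pg <- which(presence, arr.ind = TRUE)
  if (nrow(pg) > 0) {
    phrase <- character(nrow(pg))
    for (g in seq_len(G)) {
      sel <- which(pg[, 2] == g)
      if (length(sel) == 0) next
      spec <- config$groups[[g]]
      coll <- length(spec$colloquial) > 0 &
        (stats::runif(length(sel)) < config$colloquial_rate)
      canon <- tolower(spec$phrases)
      collp <- tolower(spec$colloquial)
      phrase[sel] <- ifelse(
        coll,
        collp[sample.int(max(length(collp), 1), length(sel), replace = TRUE)],
        canon[sample.int(length(canon), length(sel), replace = TRUE)]
      )
    }
    tmpl <- sample.int(length(ADR_TEMPLATES), nrow(pg), replace = TRUE)
    rows$adr <- tibble::tibble(
      post = pg[, 1],
      text = sprintf(ADR_TEMPLATES[tmpl], phrase),
      phrase = phrase,
      prefix = template_prefix(ADR_TEMPLATES)[tmpl],
      label = "ADR"
    )
  }
  # indication sentences
  ind_post <- which(stats::runif(P) < config$indication_rate)
  if (length(ind_post) > 0) {
    ph <- IND_PHRASES[sample.int(length(IND_PHRASES), length(ind_post),
                                 replace = TRUE)]
    tmpl <- sample.int(length(IND_TEMPLATES), length(ind_post), replace = TRUE)
    rows$ind <- tibble::tibble(
      post = ind_post,
      text = sprintf(IND_TEMPLATES[tmpl], ph),
      phrase = ph,
      prefix = template_prefix(IND_TEMPLATES)[tmpl],
      label = "IND"
    )
  }
  # filler: one guaranteed per post plus occasional extras
  extra <- which(stats::runif(P) < 0.5)
  fill_post <- c(seq_len(P), extra)
  rows$fill <- tibble::tibble(
    post = fill_post,
    text = FILLER_SENTENCES[sample.int(length(FILLER_SENTENCES),
                                       length(fill_post), replace = TRUE)],
    phrase = NA_character_, prefix = NA_integer_, label = NA_character_
  )

  sent <- dplyr::bind_rows(rows)
  sent$order_key <- stats::runif(nrow(sent))
  sent <- dplyr::arrange(sent, .data$post, .data$order_key)
  sent <- sent |>
    dplyr::group_by(.data$post) |>
    dplyr::mutate(sent_start = cumsum(c(0L, utils::head(nchar(.data$text) + 1L,
                                                        -1L)))) |>
    dplyr::ungroup()

  bodies <- tapply(sent$text, factor(sent$post, levels = seq_len(P)),
                   paste, collapse = " ")
  posts <- tibble::tibble(post_id = post_id, user_id = user_of_post,
                          created_at = created_at,
                          body = as.character(bodies))

  sp <- sent[!is.na(sent$label), ]
  spans <- tibble::tibble(
    post_id = post_id[sp$post],
    char_start = sp$sent_start + sp$prefix,
    char_end = sp$sent_start + sp$prefix + nchar(sp$phrase),
    label = sp$label,
    surface = sp$phrase
  ) |> dplyr::arrange(.data$post_id, .data$char_start)

  aliases <- dplyr::bind_rows(
    tibble::tibble(drug_id = drugs$drug_id, alias = tolower(drugs$drug_id)),
    tibble::tibble(drug_id = drugs$drug_id,
                   alias = tolower(drugs$brand))[!is.na(drugs$brand), ]
  ) |> dplyr::arrange(.data$drug_id, .data$alias)

  structure(list(posts = posts, spans = spans, pairs = pairs,
                 aliases = aliases, config = config),
            class = "gold_bundle")
}

#' @export
print.gold_bundle <- function(x, ...) {
  cat("<gold_bundle> ", nrow(x$posts), " posts by ",
      dplyr::n_distinct(x$posts$user_id), " users; ",
      nrow(x$spans), " gold spans; ", nrow(x$pairs), " gold pair records\n",
      sep = "")
  invisible(x)
}

#' Closed-form expected proportional reporting ratio under a configuration
#'
#' Computes the expected value of each of the four unique-user counts via
#' per-user inclusion probabilities (posts are independent given the Poisson
#' post count, so a user's probability of contributing to a count is
#' `1 - exp(-lambda * q)` with `q` the per-post event probability), and
#' combines them by the PRR formula. This is a plug-in approximation to the
#' expectation of the PRR estimator; it is exact in the large-user limit.
#'
#' The comparison set is the configuration's comparison drugs (excluding the
#' queried drug); the "any drug except D" count runs over all other drugs.
#'
#' @param config A [gen_config()].
#' @param drug,group The pair to evaluate.
#' @return The expected PRR (scalar).
#' @export
expected_prr <- function(config, drug, group) {
  stopifnot(inherits(config, "gen_config"))
  drugs <- config$drugs
  group_ids <- names(config$groups)
  stopifnot(drug %in% drugs$drug_id, group %in% group_ids)
  m <- setNames(drugs$mention_prob, drugs$drug_id)
  EM <- emission_matrix(config)
  lambda <- config$posts_per_user_mean
  ids <- drugs$drug_id
  comp <- setdiff(ids[drugs$role == "comparison"], drug)
  others <- setdiff(ids, drug)

  # P(group g present in a post) contributions
  g <- group
  # q_dr: drug mentioned AND g present
  q_dr <- m[drug] *
    (1 - (1 - EM[drug, g]) * prod(1 - m[others] * EM[others, g]))
  # a_d: drug mentioned AND any group present
  none_given_d <- prod(1 - EM[drug, ]) *
    prod(1 - m[others] * (1 - apply(1 - EM[others, , drop = FALSE], 1, prod)))
  a_d <- m[drug] * (1 - none_given_d)
  # u: some comparison drug mentioned AND g present
  p_g <- 1 - prod(1 - m[ids] * EM[ids, g])
  noncomp <- setdiff(ids, comp)
  p_g_nocomp <- prod(1 - m[comp]) *
    (1 - prod(1 - m[noncomp] * EM[noncomp, g]))
  u <- p_g - p_g_nocomp
  # v: some non-D drug mentioned AND any group present
  p_any <- 1 - prod(1 - m[ids] * (1 - apply(1 - EM[ids, , drop = FALSE], 1, prod)))
  p_any_onlyd <- prod(1 - m[others]) * m[drug] * (1 - prod(1 - EM[drug, ]))
  v <- p_any - p_any_onlyd

  incl <- function(q) 1 - exp(-lambda * q)
  e_ndr <- config$n_users * incl(q_dr)
  e_nd <- config$n_users * incl(a_d)
  e_nnotdr <- config$n_users * incl(u)
  e_nnotd <- config$n_users * incl(v)
  if (e_nd <= 0 || e_nnotd <= 0) {
    stop_adr("Expected n_d and n_notd must be positive under this configuration.",
             "adrsignal_undefined_prr")
  }
  unname((e_ndr / e_nd) / (e_nnotdr / e_nnotd))
}

#' Benchmark corpus configurations
#'
#' `demo_gen_config()` is the planted-association scenario: one target drug
#' (erlotinib, brand Tarceva) against nine comparison drugs, uniform 3%
#' per-post mention probability, 1% background pair-report rate, and a single
#' planted pair — erlotinib with hypohidrosis at a 20% conditional report
#' rate — whose closed-form expected PRR is approximately 4.
#' `null_gen_config()` is the exchangeable null: 20 drugs (one nominally
#' target, 19 comparison) times the eight reaction groups with every
#' emission rate equal, used to check false-positive control of the
#' calibrated threshold.
#'
#' @param n_users Number of users (default 5000).
#' @param seed Integer seed.
#' @return A [gen_config()].
#' @export
demo_gen_config <- function(n_users = 5000L, seed = 1L) {
  gen_config(
    n_users = n_users,
    planted = tibble::tibble(drug_id = "erlotinib",
                             group_id = "hypohidrosis",
                             emission_prob = 0.2),
    seed = seed
  )
}

#' @rdname demo_gen_config
#' @export
null_gen_config <- function(n_users = 5000L, seed = 1L) {
  gen_config(
    n_users = n_users,
    drugs = tibble::tibble(
      drug_id = sprintf("drug%02d", 1:20),
      role = c("target", rep("comparison", 19)),
      mention_prob = 0.05,
      brand = NA_character_
    ),
    background_emission = 0.02,
    planted = NULL,
    seed = seed
  )
}

#' Write the lexicon fixture files for the default (or custom) groups
#'
#' Emits a consistent ontology, seed table, expanded lexicon and colloquial
#' phrase file that round-trip through the concept normalizer: every group's
#' seed with synonyms, the "nail changes" is-a subtree (including an
#' ingrown-toenail-style child and a peeling-of-nails entry), and the
#' colloquial phrases. These files are synthetic stand-ins for a licensed
#' concept source, generated from [default_group_specs()].
#'
#' @param dir Output directory (created if needed).
#' @param groups Group specifications (default [default_group_specs()]).
#' @return List with `paths` (named file paths: `ontology`, `seeds`,
#'   `lexicon`, `colloquial`) and the in-memory `lexicon`, `ontology`,
#'   `seeds` and `colloquial` tibbles.
#' @export
generate_lexicon_fixture <- function(dir = tempfile("lexicon"),
                                     groups = default_group_specs()) {
  stopifnot(length(groups) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ont_rows <- purrr::map(groups, function(sp) {
    seed <- tibble::tibble(
      concept_id = sp$seed_concept_id, preferred_name = sp$seed_name,
      synonyms = paste(sp$synonyms, collapse = "|"), parents = ""
    )
    kids <- purrr::map(sp$children %||% list(), function(ch) {
      tibble::tibble(concept_id = ch$concept_id, preferred_name = ch$name,
                     synonyms = paste(ch$synonyms, collapse = "|"),
                     parents = sp$seed_concept_id)
    }) |> dplyr::bind_rows()
    dplyr::bind_rows(seed, kids)
  }) |> dplyr::bind_rows()

  seeds <- purrr::map(groups, function(sp) {
    tibble::tibble(concept_id = sp$seed_concept_id, group_id = sp$group_id,
                   expand_children = isTRUE(sp$expand_children))
  }) |> dplyr::bind_rows()

  colloquial <- purrr::map(groups, function(sp) {
    if (length(sp$colloquial) == 0) return(NULL)
    tibble::tibble(phrase = sp$colloquial, group_id = sp$group_id)
  }) |> dplyr::bind_rows()

  paths <- list(
    ontology = file.path(dir, "ontology.tsv"),
    seeds = file.path(dir, "seeds.tsv"),
    lexicon = file.path(dir, "lexicon.tsv"),
    colloquial = file.path(dir, "colloquial.tsv")
  )
  readr::write_tsv(ont_rows, paths$ontology, progress = FALSE)
  readr::write_tsv(seeds, paths$seeds, progress = FALSE)
  readr::write_tsv(colloquial, paths$colloquial, progress = FALSE)

  ontology <- read_ontology(paths$ontology)
  lexicon <- expand_lexicon(seeds, ontology, colloquial)
  write_lexicon(lexicon, paths$lexicon)

  list(paths = paths, lexicon = lexicon, ontology = ontology, seeds = seeds,
       colloquial = colloquial)
}
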