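#' Built-in toy metabolic model
#'
#' A small, fully deterministic metabolic model for examples, tests and
#' simulation: 45 real small molecules with true monoisotopic masses
#' (computed from CODATA atomic masses) organised into nine partially
#' overlapping pathways of human central metabolism, each annotated with
#' gene symbols and UniProt accessions for the multi-omics overlay. It is
#' deliberately tiny — a stand-in for a genome-scale model such as
#' mummichog's human network, which users can substitute via
#' [read_metabolic_model()].
#'
#' @return A [metabolic_model()] with 45 compounds and 9 pathways. Calling
#'   the function twice yields identical objects.
#' @export
#' @examples
#' m <- toy_metabolic_model()
#' m$pathways$name
toy_metabolic_model <- function() {
  compounds <- tibble::tribble(
    ~id,                ~name,                        ~monoisotopic_mass, ~aliases,
    "glucose",          "glucose",                    180.063388, "D-glucose;dextrose",
    "g6p",              "glucose 6-phosphate",        260.029719, "",
    "pyruvate",         "pyruvate",                    88.016044, "pyruvic acid",
    "lactate",          "lactate",                     90.031694, "lactic acid",
    "citrate",          "citrate",                    192.027003, "citric acid",
    "succinate",        "succinate",                  118.026609, "succinic acid",
    "fumarate",         "fumarate",                   116.010959, "fumaric acid",
    "malate",           "malate",                     134.021523, "malic acid",
    "akg",              "alpha-ketoglutarate",        146.021523, "2-oxoglutarate",
    "oaa",              "oxaloacetate",               132.005873, "",
    "glycine",          "glycine",                     75.032028, "",
    "alanine",          "alanine",                     89.047678, "L-alanine",
    "serine",           "serine",                     105.042593, "L-serine",
    "cysteine",         "cysteine",                   121.019749, "L-cysteine",
    "methionine",       "methionine",                 149.051049, "L-methionine",
    "aspartate",        "aspartate",                  133.037508, "aspartic acid",
    "asparagine",       "asparagine",                 132.053492, "",
    "glutamate",        "glutamate",                  147.053158, "glutamic acid",
    "glutamine",        "glutamine",                  146.069142, "",
    "tyrosine",         "tyrosine",                   181.073893, "L-tyrosine",
    "phenylalanine",    "phenylalanine",              165.078979, "L-phenylalanine",
    "tryptophan",       "tryptophan",                 204.089878, "L-tryptophan",
    "arginine",         "arginine",                   174.111676, "L-arginine",
    "ornithine",        "ornithine",                  132.089878, "L-ornithine",
    "citrulline",       "citrulline",                 175.095791, "",
    "proline",          "proline",                    115.063329, "L-proline",
    "taurine",          "taurine",                    125.014664, "2-aminoethanesulfonic acid",
    "hypotaurine",      "hypotaurine",                109.019749, "",
    "putrescine",       "putrescine",                  88.100048, "",
    "spermidine",       "spermidine",                 145.157898, "",
    "spermine",         "spermine",                   202.215747, "",
    "acetylspermidine", "N1-acetylspermidine",        187.168462, "",
    "acetylspermine",   "N1-acetylspermine",          244.226311, "",
    "adenine",          "adenine",                    135.054495, "",
    "guanine",          "guanine",                    151.049410, "",
    "hypoxanthine",     "hypoxanthine",               136.038511, "",
    "xanthine",         "xanthine",                   152.033425, "",
    "urate",            "uric acid",                  168.028340, "urate",
    "inosine",          "inosine",                    268.080770, "",
    "adenosine",        "adenosine",                  267.096754, "",
    "cholate",          "cholic acid",                408.287574, "cholate",
    "cdca",             "chenodeoxycholic acid",      392.292660, "chenodeoxycholate",
    "taurocholate",     "taurocholic acid",           515.291673, "",
    "tcdca",            "taurochenodeoxycholic acid", 499.296759, "taurochenodeoxycholate",
    "glycocholate",     "glycocholic acid",           465.309123, ""
  )

  pathways <- tibble::tribble(
    ~id,  ~name,                                ~compound_ids,                          ~gene_symbols,              ~uniprot_ids,
    "P1", "Glycolysis and gluconeogenesis",
      "glucose;g6p;pyruvate;lactate",
      "HK1;GPI;PKM;LDHA",         "P19367;P06744;P14618;P00338",
    "P2", "TCA cycle",
      "pyruvate;citrate;succinate;fumarate;malate;akg;oaa;lactate",
      "CS;SDHA;FH;MDH2;IDH1",     "O75390;P31040;P07954;P40926",
    "P3", "Bile acid biosynthesis",
      "cholate;cdca;taurocholate;tcdca;glycocholate;taurine;glycine;cysteine",
      "CYP7A1;CYP27A1;BAAT;SLC10A1", "P22680;Q02318;Q14032;Q14973",
    "P4", "Polyamine metabolism",
      "ornithine;putrescine;spermidine;spermine;acetylspermidine;acetylspermine;methionine",
      "ODC1;SAT1;SMS;SRM;AMD1",   "P11926;P21673;P52788;P19623",
    "P5", "Aspartate and asparagine metabolism",
      "aspartate;asparagine;glutamate;glutamine;oaa;fumarate",
      "ASNS;ASPA;GOT1;GOT2",      "P08243;P45381;P17174;P00505",
    "P6", "Glycine, serine and alanine metabolism",
      "glycine;serine;alanine;cysteine;pyruvate;taurine;hypotaurine",
      "SHMT1;SHMT2;GLDC;AGXT",    "P34896;P34897;P23378;P21549",
    "P7", "Purine metabolism",
      "adenine;guanine;hypoxanthine;xanthine;urate;inosine;adenosine;glutamine;glycine",
      "PPAT;XDH;HPRT1;ADA",       "Q06203;P47989;P00492;P00813",
    "P8", "Urea cycle",
      "arginine;ornithine;citrulline;aspartate;fumarate;glutamate",
      "ASS1;ASL;ARG1;OTC;CPS1",   "P00966;P04424;P05089;P00480",
    "P9", "Tyrosine and tryptophan metabolism",
      "tyrosine;phenylalanine;tryptophan",
      "TAT;TH;TPH1;IDO1",         "P17735;P07101;P17752;P14902"
  )

  metabolic_model(compounds, pathways,
                  metadata = list(name = "pathmeta toy model",
                                  version = "1.0"))
}
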