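# bgclineage

Comparative analysis of modular **non-ribosomal peptide synthetase (NRPS)**
and **type-I polyketide synthase (PKS)** biosynthetic gene clusters from
domain-organization annotations, built around the complete cluster inventory
of the five *Herbidospora* type strains (*H. cretacea*, *H. mongoliensis*,
*H. yilanensis*, *H. daliensis*, *H. sakaeratensis*), which ships with the
package as a plain-text table.

NRPS and type-I PKS megasynthases are organized into **modules**, each
carrying out one cycle of chain elongation — minimally C/A/T domains for an
NRPS module and KS/AT/ACP for a PKS module. Under the **assembly-line
rule**, module order is collinear with product structure, so the backbone of
the peptide or polyketide can be read off the domain organization: the A
domain picks the amino acid, the AT domain picks the extender unit
(malonyl-CoA → R = H, methylmalonyl-CoA → R = CH3, ethylmalonyl-CoA →
R = C2H5), and the β-keto group left by each condensation is processed by
the module's optional reduction domains:

    {}        -> ketone        C(=O)
    {KR}      -> hydroxyl      CH(OH)
    {KR,DH}   -> C=C double bond
    {KR,DH,ER}-> fully reduced CH2

The package provides, for users studying secondary-metabolite potential in
actinomycete genomes:

* a parser/formatter for the compact domain-string notation
  (`C/A_asp/T-TE`, `KS/AT_e(m)/DH/KR/ACP`, truncation marks, tentative
  calls) with a closed substrate vocabulary — `parse_domain_string()`,
  `format_domain_string()`;
* assembly-line reconstruction: gene ordering (loading module first, TE
  last), module segmentation across gene boundaries, module counting with
  lower-bound semantics for partially sequenced clusters —
  `segment_modules()`, `count_modules()`;
* backbone prediction and chemistry summaries (`predict_backbone()`,
  `summarize_chemistry()`, SMILES/residue output via
  `backbone_to_linear_notation()`);
* cross-strain ortholog grouping by shared closest homolog plus
  domain-organization similarity, with presence/absence matrices —
  `group_orthologs()`, `classify_sharing()`, `presence_matrix()`;
* distance phylogenetics (p/JC69 with pairwise deletion, neighbor joining,
  bootstrap, Robinson–Foulds, outgroup rooting) — `nj_tree()`,
  `bootstrap_support()`, `rf_distance()`;
* Dollo-parsimony gain/loss reconstruction of pathway history on the
  species tree — `dollo_map()`, `summarize_events()`;
* seeded simulators with known ground truth for every stage —
  `simulate_inventory()`, `simulate_presence_evolution()`,
  `simulate_alignment()`.

## Worked example

```r
library(bgclineage)

inv <- load_cluster_table(bgc_example_table())
inventory_summary(inv)
#>           strain nrps hybrid pks total
#>       H_cretacea    9      1   5    15
#>   H_mongoliensis    9      2   6    17
#>     H_yilanensis    9      2   4    15
#>      H_daliensis   10      1   4    15
#>  H_sakaeratensis   12      2   4    18

# the largest type-I PKS cluster: 35 modules over 12 genes
count_modules(segment_modules(find_cluster(inv, "H_cretacea", "pks-6")))$total
#> [1] 35

# read a siderophore-like peptide off its assembly line
bb <- predict_backbone(segment_modules(find_cluster(inv, "H_cretacea", "nrps-1")))
backbone_product_string(bb)
#> [1] "x-Ser-mOrn-x-Ser-x"   # x = A domain with unpredicted substrate

# 32 pathways: 9 in all five strains, 8 in 2-4 strains, 15 strain-specific
groups <- group_orthologs(inv, threshold = 0.8)
classify_sharing(groups, names(inv))[c("universal", "partial", "specific")]
#> $universal [1] 9   $partial [1] 8   $specific [1] 15

# gain/loss history on the species tree
tree <- root_with_outgroup(ape::read.tree(bgc_example_tree()),
                           "A_corrugata", prune = TRUE)
pres <- presence_matrix(groups, names(inv))
dollo_map(tree, pres["pks-2", ])[c("gain_branch", "loss_branches")]
#> $gain_branch  "H_cretacea+H_daliensis+H_mongoliensis+H_sakaeratensis+H_yilanensis"
#> $loss_branches "H_cretacea"   # gained at the genus root, lost in H. cretacea
```

The numbered scripts under `analysis/` run the complete study —
inventory, module segmentation and product prediction, ortholog grouping,
tree verification, gain/loss mapping — and write their tables under
`results/`:

```sh
Rscript analysis/01_inventory.R
Rscript analysis/02_modules_products.R
# ... through analysis/05_gain_loss.R
```

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantities of the analysis
from scratch against the installed package — ortholog-group sharing counts,
module counts of the largest clusters, and backbone feature counts — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
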