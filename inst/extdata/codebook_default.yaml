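# Default thematic codebook: labels follow the use categories observed in
# wildlife-product patenting (novel products and trade-process innovations)
# with starter keywords in the spirit of economic-botany use-category term
# lists. This is a synthetic, configurable stand-in term list, not the
# external collection standard itself; pipelines normally extend it with
# LDA top terms and expansion-iteration keywords.
medicine:
  keywords: [medicine, medicinal, treating, treatment, therapy, disorders,
             pain, pharmaceutical, tablet, capsule, decoction]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term, standard_term]
food:
  keywords: [food, beverage, drink, nutrition, nutritional, soup, caviar,
             health food]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term, standard_term, standard_term]
cosmetics:
  keywords: [cosmetic, cosmetics, skin care, cream, toothpaste, beautifying]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term]
synthetics:
  keywords: [synthetic, artificial, recombinant, analogue, substitute,
             fermentation]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term]
farming:
  keywords: [farming, breeding, culturing, feed, rearing, cultivation,
             aquaculture]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term, standard_term]
processing:
  keywords: [processing, preparation method, extraction, concocting,
             powder preparation]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term]
detection:
  keywords: [detection, identifying, identification, authenticity,
             polymerase chain reaction, counterfeit]
  provenance: [standard_term, standard_term, standard_term, standard_term,
               standard_term, standard_term]
agriculture:
  keywords: [fertilizer, pesticide, livestock, crop]
  provenance: [standard_term, standard_term, standard_term, standard_term]
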