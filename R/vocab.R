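# Closed vocabulary for the bundled rule parser and the synthetic-text
# templates. The tagger resolves a token by dictionary membership in the
# order below; anything unrecognized defaults to a noun, the safe choice for
# term-frequency counting (an unknown noun never forms an opinion pair
# unless an adjective links to it).

DICT_DET <- c(
  "a", "an", "the", "this", "that", "these", "those", "some", "any",
  "such", "another", "all", "my", "your", "his", "her", "its", "our", "their"
)
DICT_PRON <- c(
  "i", "me", "you", "it", "he", "she", "we", "they", "him", "us", "them"
)
DICT_COPULA <- c(
  "is", "are", "was", "were", "am", "be", "been", "being",
  "seems", "seemed", "feels", "felt"
)
DICT_ADV <- c(
  "really", "very", "definitely", "too", "so", "quite", "extremely",
  "absolutely", "overall", "pretty", "super", "rather", "just", "still",
  "always", "never", "not", "again", "soon", "forever", "here", "there"
)
DICT_PREP <- c(
  "with", "like", "for", "of", "in", "on", "to", "from", "at", "as", "by",
  "about", "after", "before", "over", "under", "out", "up", "down"
)
DICT_CONJ <- c("and", "or", "but")
DICT_VERB <- c(
  "makes", "make", "made", "take", "takes", "took", "stands", "looks",
  "gets", "got", "love", "loved", "likes", "hate", "hated", "tried", "try",
  "bought", "buy", "ordered", "order", "recommended", "recommend", "mixed",
  "keep", "keeps", "kept", "gives", "gave", "arrived", "shipped", "works",
  "worked", "lasted", "tastes", "smells", "came", "come", "cough", "coughs",
  "will", "would", "can", "could", "vaped", "vaping"
)
# Non-polarity adjectives known to the tagger (polarity adjectives come from
# the sentiment lexicon at parse time).
DICT_EXTRA_ADJ <- c("purple", "green", "blue", "red", "new", "own")

# Adjectives the generator plants, split by polarity; every entry is in the
# bundled lexicon with the matching polarity.
PLANT_POS_ADJ <- c(
  "great", "good", "nice", "strong", "sweet", "smooth", "excellent",
  "tasty", "reasonable", "perfect", "amazing", "wonderful"
)
PLANT_NEG_ADJ <- c(
  "harsh", "weak", "bad", "terrible", "sour", "bitter", "steep",
  "expensive", "soapy", "odd", "strange", "unpleasant", "poor", "nasty"
)

# Distractor sentences: non-aspect nouns only, no adjectives, no copulas, so
# they can never yield an opinion pair under the two sanctioned patterns.
DISTRACTOR_SENTENCES <- c(
  "I ordered another bottle from the store.",
  "The shipping took two weeks.",
  "My friend recommended this brand to me.",
  "Definitely an adv for me.",
  "I keep it in my tank all day.",
  "Will order again soon."
)
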