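# Regex component of the parenthetical classification cascade, v1.
# category <TAB> perl-compatible regex matched against the span content.
# Structural rules (attachment to the preceding word, token counts, left
# context) are applied in code; see ?classify_paren. Lines starting with
# '#' are comments. Order within a category is OR; cascade precedence is
# fixed in code.
citation	^(?:[A-Z][A-Za-z'-]+(?:\s+(?:and|&)\s+[A-Z][A-Za-z'-]+)?(?:,?\s+et\s+al\.?)?,?\s+(?:19|20)\d\d[a-z]?)(?:\s*;\s*[A-Z][A-Za-z'-]+(?:\s+(?:and|&)\s+[A-Z][A-Za-z'-]+)?(?:,?\s+et\s+al\.?)?,?\s+(?:19|20)\d\d[a-z]?)*$
citation	^\[?\d{1,3}(?:\s*[-,]\s*\d{1,3})*\]$
figure_table_pointer	^(?i:see\s+)?(?i:fig(?:ure)?s?|table?s?|tab)\.?\s*\S?\d+[A-Za-z]?(?:\s*[-,and\s]+\s*\S?\d*[A-Za-z]?)*$
p_value	^(?i:p)\s*(?:value)?\s*[<>=≤≥]+\s*\.?\d
list_enumerator	^(?:[A-Za-z]|[ivxlcdm]+|[IVXLCDM]+|\d{1,2})$
data_value	^[^=<>]{0,30}[=<>≤≥±][^=<>]{0,30}$
data_value	^[-+]?\d[\d.,]*\s*(?:%|°C|mg|ml|mm|nm|kg|g|kb|bp|h|min|s)?$
data_value	^(?:[nN]|df|r2?|R2?|h2|F|t|z|LRS|LOD)\s*[=<>]
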