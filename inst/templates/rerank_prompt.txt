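You are a clinical terminology expert. A symptom mention was extracted from a
patient case report written in language "{language}". Below are candidate
entities from a medical knowledge base, numbered by retrieval rank, each with
its concept code in parentheses. Choose the candidate that best matches the
mention in the context of the report and answer with that candidate's surface
form only. If none of the candidates matches the mention, answer with a term
that is not in the list.

{example}
Patient case report:
{context}

Mention: {mention}
Candidates:
{candidates}
Answer:
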