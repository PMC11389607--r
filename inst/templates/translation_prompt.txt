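Translate the following symptom mention from language "{source_language}"
into Spanish. Answer with the Spanish translation only, nothing else.

Mention: "{mention}"
Spanish translation:
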