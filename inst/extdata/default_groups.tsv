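subsumer	name	exclude	reference	model
554915	Amoebozoa		142796	44689
2157	Archaea		183963	2243
2	Bacteria		1236	562
7711	Chordata		40674	9606
4751	Fungi		4891	4932
33317	Metazoa excluding Chordata	7711	50557	7227
33090	Viridiplantae		71240	3702
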