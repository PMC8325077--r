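Mary
Patricia
Jennifer
Linda
Elizabeth
Barbara
Susan
Jessica
Sarah
Karen
Nancy
Lisa
Betty
Margaret
Sandra
Ashley
Kimberly
Emily
Donna
Michelle
Carol
Amanda
Dorothy
Melissa
Deborah
Stephanie
Rebecca
Sharon
Laura
Cynthia
Kathleen
Amy
Angela
Shirley
Anna
Brenda
Pamela
Emma
Nicole
Helen
Samantha
Katherine
Christine
Debra
Rachel
Carolyn
Janet
Catherine
Maria
Heather
Diane
Ruth
Julie
Olivia
Joyce
Virginia
Victoria
Kelly
Lauren
Christina
Joan
Evelyn
Judith
Megan
Andrea
Cheryl
Hannah
Jacqueline
Martha
Gloria
Teresa
Ann
Sara
Madison
Frances
Kathryn
Janice
Jean
Alice
Abigail
Julia
Judy
Sophia
Grace
Denise
Amber
Doris
Marilyn
Danielle
Beverly
Isabella
Theresa
Diana
Natalie
Brittany
Charlotte
Marie
Kayla
Alexis
Lori
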